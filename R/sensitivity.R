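#' One-at-a-time sensitivity scan of an optimization output
#'
#' Re-solves the design optimization with each parameter perturbed in turn
#' to each of the multiplier levels (defaults L1 = 0.5, L2 = 0.9,
#' U1 = 1.1, U2 = 1.5) and records the relative change of the optimum,
#' `delta = (f*_perturbed - f*_nominal) / f*_nominal`. Parameters whose
#' largest `|delta|` across levels reaches `flag_threshold` (default 10%)
#' are flagged as influential. A perturbation under which the optimizer is
#' infeasible is recorded as such, not dropped.
#'
#' @param registry Parameter registry; scanned parameters default to all
#'   of its ids.
#' @param optimizer Function taking a named multiplier vector and returning
#'   the perturbed optimal objective `f*` (a number; `NA` if infeasible).
#' @param levels Multiplier levels to scan.
#' @param ids Subset of parameter ids to scan (default: all).
#' @param flag_threshold Flag if `max |delta| >=` this value.
#' @return Object of class `hd_scan`: data frame `records` (`param`,
#'   `level`, `f_opt`, `delta`, `infeasible`), `f_nominal`, and `flagged`
#'   (character vector of influential parameter ids).
#' @export
univariate_scan <- function(registry, optimizer,
                            levels = c(0.5, 0.9, 1.1, 1.5),
                            ids = registry$id, flag_threshold = 0.10) {
  f_nom <- optimizer(stats::setNames(numeric(0), character(0)))
  if (!is.finite(f_nom) || f_nom <= 0)
    stop("nominal optimum must exist and be positive", call. = FALSE)
  rec <- expand.grid(level = levels, param = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- rec[, c("param", "level")]
  rec$f_opt <- NA_real_
  for (i in seq_len(nrow(rec))) {
    mult <- stats::setNames(rec$level[i], rec$param[i])
    rec$f_opt[i] <- tryCatch(optimizer(mult), error = function(e) NA_real_)
  }
  rec$infeasible <- !is.finite(rec$f_opt)
  rec$delta <- (rec$f_opt - f_nom) / f_nom
  agg <- tapply(abs(rec$delta), rec$param, max, na.rm = TRUE)
  agg[!is.finite(agg)] <- NA
  flagged <- sort(names(agg)[!is.na(agg) & agg >= flag_threshold])
  structure(list(records = rec, f_nominal = f_nom, flagged = flagged,
                 flag_threshold = flag_threshold),
            class = "hd_scan")
}

#' Two-at-a-time interaction sensitivity
#'
#' For each parameter pair and level pair, `S_ij = delta_ij - delta_i -
#' delta_j`: the excess of the joint relative change over the sum of the
#' univariate changes. For a linear-in-parameters optimization output
#' `S_ij` is identically zero, so large `|S_ij|` flags nonlinear parameter
#' interaction. Pairs whose largest `|S_ij|` across level pairs exceeds
#' `flag_threshold` (default 15%) are flagged. Storage is symmetric:
#' `S_ij` is recorded once per unordered pair with `param_i < param_j`.
#'
#' @param registry Parameter registry.
#' @param optimizer As in [univariate_scan()].
#' @param pairs Two-column matrix or data frame of parameter-id pairs;
#'   default all `choose(n, 2)` pairs of `ids`.
#' @param levels Multiplier levels.
#' @param uni Optional precomputed `hd_scan` from [univariate_scan()] over
#'   the same ids and levels (computed if missing).
#' @param ids Parameter ids used when `pairs` is not given.
#' @param flag_threshold Flag if `max |S_ij|` > this value.
#' @return Object of class `hd_scan2`: data frame `records` (`param_i`,
#'   `param_j`, `level_i`, `level_j`, `delta_ij`, `s_ij`, `infeasible`),
#'   `flagged` (data frame of flagged pairs), `f_nominal`.
#' @export
bivariate_scan <- function(registry, optimizer, pairs = NULL,
                           levels = c(0.5, 0.9, 1.1, 1.5),
                           uni = NULL, ids = registry$id,
                           flag_threshold = 0.15) {
  if (is.null(pairs)) {
    cmb <- utils::combn(sort(ids), 2)
    pairs <- data.frame(param_i = cmb[1, ], param_j = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs) <- c("param_i", "param_j")
    swap <- pairs$param_i > pairs$param_j
    tmp <- pairs$param_i[swap]
    pairs$param_i[swap] <- pairs$param_j[swap]
    pairs$param_j[swap] <- tmp
    pairs <- unique(pairs)
  }
  scan_ids <- unique(c(pairs$param_i, pairs$param_j))
  if (is.null(uni))
    uni <- univariate_scan(registry, optimizer, levels, ids = scan_ids)
  f_nom <- uni$f_nominal
  uni_delta <- function(p, l) {
    r <- uni$records
    d <- r$delta[r$param == p & r$level == l]
    if (!length(d)) stop("univariate delta missing for ", p, " at level ",
                         l, call. = FALSE)
    d[1]
  }
  out <- list()
  for (pi in seq_len(nrow(pairs))) {
    p1 <- pairs$param_i[pi]; p2 <- pairs$param_j[pi]
    for (l1 in levels) for (l2 in levels) {
      mult <- stats::setNames(c(l1, l2), c(p1, p2))
      f12 <- tryCatch(optimizer(mult), error = function(e) NA_real_)
      d12 <- (f12 - f_nom) / f_nom
      s <- d12 - uni_delta(p1, l1) - uni_delta(p2, l2)
      out[[length(out) + 1L]] <- data.frame(
        param_i = p1, param_j = p2, level_i = l1, level_j = l2,
        delta_ij = d12, s_ij = s, infeasible = !is.finite(f12),
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, out)
  key <- paste(rec$param_i, rec$param_j, sep = ":")
  agg <- tapply(abs(rec$s_ij), key, max, na.rm = TRUE)
  agg[!is.finite(agg)] <- NA
  fl <- names(agg)[!is.na(agg) & agg > flag_threshold]
  flagged <- if (length(fl)) {
    sp <- strsplit(sort(fl), ":", fixed = TRUE)
    data.frame(param_i = vapply(sp, `[`, "", 1),
               param_j = vapply(sp, `[`, "", 2),
               max_abs_s = unname(agg[sort(fl)]),
               stringsAsFactors = FALSE)
  } else data.frame(param_i = character(0), param_j = character(0),
                    max_abs_s = numeric(0))
  structure(list(records = rec, flagged = flagged, f_nominal = f_nom,
                 flag_threshold = flag_threshold),
            class = "hd_scan2")
}

#' Scan-budget combinatorics
#'
#' Number of k-parameter combinations and the projected CPU cost of a full
#' k-at-a-time scan at the given number of levels per parameter and
#' seconds per optimization run:
#' `cpu_days = choose(n_params, k) * n_levels^k * seconds_per_run / 86400`.
#'
#' @param n_params Number of scanned parameters.
#' @param k Parameters perturbed jointly.
#' @param n_levels Levels per parameter.
#' @param seconds_per_run Wall seconds per optimization run.
#' @return List with `n_combinations` and `cpu_days`.
#' @examples
#' scan_budget(30, 2, 4, 300)  # 435 pairs, ~24.2 CPU days
#' @export
scan_budget <- function(n_params, k, n_levels, seconds_per_run) {
  stopifnot(k >= 1, k <= n_params, n_levels >= 1, seconds_per_run >= 0)
  n_comb <- choose(n_params, k)
  list(n_combinations = n_comb,
       cpu_days = n_comb * n_levels^k * seconds_per_run / 86400)
}

#' Rank scanned parameters by induced variability
#'
#' Stable descending sort of parameters (or pairs) by the largest absolute
#' effect across levels; ties broken alphabetically by id.
#'
#' @param scan An `hd_scan` or `hd_scan2`.
#' @return Data frame `param` (or `param_i`,`param_j`) and `max_abs_effect`,
#'   ordered.
#' @export
rank_sensitivity <- function(scan) {
  if (inherits(scan, "hd_scan")) {
    agg <- tapply(abs(scan$records$delta), scan$records$param, max,
                  na.rm = TRUE)
    agg[!is.finite(agg)] <- NA
    out <- data.frame(param = names(agg), max_abs_effect = as.numeric(agg),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$max_abs_effect, out$param), ]
  } else if (inherits(scan, "hd_scan2")) {
    key <- paste(scan$records$param_i, scan$records$param_j, sep = ":")
    agg <- tapply(abs(scan$records$s_ij), key, max, na.rm = TRUE)
    agg[!is.finite(agg)] <- NA
    sp <- strsplit(names(agg), ":", fixed = TRUE)
    out <- data.frame(param_i = vapply(sp, `[`, "", 1),
                      param_j = vapply(sp, `[`, "", 2),
                      max_abs_effect = as.numeric(agg),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$max_abs_effect, out$param_i, out$param_j), ]
  } else stop("not a sensitivity scan object", call. = FALSE)
  rownames(out) <- NULL
  out
}
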