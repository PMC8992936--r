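#' Per-direction differences between sCT- and CT-based positioning
#'
#' For every case/observer pair the difference `sCT-based result - CT-based
#' result` is computed in each of the six directions (translations along
#' R-L, P-A, I-S; rotations pitch, yaw, roll), sign preserved. For 2D
#' (orthogonal-projection) rows roll is not available and is recorded as
#' `NA`.
#'
#' @param results a paired-registration data.frame as produced by
#'   [sample_paired_registrations()] (columns `case`, `observer`,
#'   `modality`, `reference`, `tx`...`roll`)
#' @return long data.frame (`case`, `observer`, `modality`, `direction`,
#'   `difference`) with direction levels `RL`, `PA`, `IS`, `pitch`, `yaw`,
#'   `roll`
#' @export
dof_differences <- function(results) {
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  dir_label <- c(tx = "RL", ty = "PA", tz = "IS",
                 pitch = "pitch", yaw = "yaw", roll = "roll")
  need <- c("case", "observer", "modality", "reference", dof)
  if (!all(need %in% names(results)))
    stop("missing columns: ", paste(setdiff(need, names(results)), collapse = ", "))
  key <- interaction(results$case, results$observer, results$modality,
                     drop = TRUE)
  out <- lapply(levels(key), function(k) {
    g <- results[key == k, ]
    ct <- g[g$reference == "ct", ]
    sct <- g[g$reference == "sct", ]
    if (nrow(ct) != 1L || nrow(sct) != 1L)
      stop("case ", g$case[1], " observer ", g$observer[1],
           " is missing a member of its ct/sct pair")
    data.frame(case = g$case[1], observer = g$observer[1],
               modality = g$modality[1],
               direction = factor(dir_label[dof],
                                  levels = unname(dir_label)),
               difference = as.numeric(sct[1, dof]) - as.numeric(ct[1, dof]))
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Per-direction summary of positioning differences
#'
#' Mean, sample SD (n-1 denominator), minimum and maximum of the
#' differences per modality and direction — the layout of the positioning
#' accuracy table. Directions with a single value report the mean with SD
#' `NA`; empty directions (e.g. roll in 2D) are omitted with a warning.
#'
#' @param table a difference table from [dof_differences()]
#' @return data.frame with columns `modality`, `direction`, `n`, `mean`,
#'   `sd`, `min`, `max`
#' @export
summarize_differences <- function(table) {
  key <- interaction(table$modality, table$direction, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    g <- table[key == k, ]
    v <- g$difference[!is.na(g$difference)]
    if (length(v) == 0L) {
      warning("no finite differences for ", g$modality[1], "/",
              g$direction[1], "; omitted")
      return(NULL)
    }
    data.frame(modality = g$modality[1], direction = g$direction[1],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(modality = character(), direction = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      min = numeric(), max = numeric()))
  out <- out[order(out$modality, out$direction), ]
  rownames(out) <- NULL
  out
}

#' Paired TOST equivalence test
#'
#' Two one-sided t-tests of the paired differences against the equivalence
#' interval `(low, high)` (default the (-1, 1) mm clinical interval):
#' `t_lower = (mean - low) / (sd / sqrt(n))` tested against
#' `P(T_{n-1} >= t_lower)` and `t_upper = (mean - high) / (sd / sqrt(n))`
#' against `P(T_{n-1} <= t_upper)`. Equivalence is declared when both
#' one-sided p-values fall below `alpha`; the overall p-value is their
#' maximum. By TOST duality this matches the `1 - 2*alpha` (90% at the
#' default) confidence interval lying inside the bounds; both the 90% and
#' 95% intervals are reported.
#'
#' @param diffs numeric vector of paired differences (mm)
#' @param low,high equivalence bounds (default -1 and +1 mm)
#' @param alpha level of each one-sided test (default 0.05)
#' @return object of class `tost_result`: `n`, `mean`, `sd`, `t_lower`,
#'   `t_upper`, `p_lower`, `p_upper`, `p_overall`, `equivalent`, `bounds`,
#'   `ci90`, `ci95`
#' @export
tost_paired <- function(diffs, low = -1, high = 1, alpha = 0.05) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 paired differences")
  if (!(low < high)) stop("`low` must be < `high`")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    warning("zero-variance differences: degenerate TOST; equivalence ",
            "decided by the mean alone")
    eq <- (m > low && m < high)
    return(structure(list(n = n, mean = m, sd = 0,
                          t_lower = Inf * sign(m - low),
                          t_upper = Inf * sign(m - high),
                          p_lower = if (m > low) 0 else 1,
                          p_upper = if (m < high) 0 else 1,
                          p_overall = if (eq) 0 else 1,
                          equivalent = eq, bounds = c(low, high),
                          ci90 = c(m, m), ci95 = c(m, m)),
                     class = "tost_result"))
  }
  se <- s / sqrt(n)
  df <- n - 1
  t_lower <- (m - low) / se
  t_upper <- (m - high) / se
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p_overall <- max(p_lower, p_upper)
  structure(list(n = n, mean = m, sd = s,
                 t_lower = t_lower, t_upper = t_upper,
                 p_lower = p_lower, p_upper = p_upper,
                 p_overall = p_overall,
                 equivalent = (p_overall < alpha),
                 bounds = c(low, high),
                 ci90 = m + c(-1, 1) * stats::qt(0.95, df) * se,
                 ci95 = m + c(-1, 1) * stats::qt(0.975, df) * se),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    paste0("tost_result: n = %d, mean = %.3f +/- %.3f, bounds (%.2f, %.2f)\n",
           "  p_lower = %.3g, p_upper = %.3g, p_overall = %.3g -> %s\n",
           "  90%% CI [%.3f, %.3f], 95%% CI [%.3f, %.3f]\n"),
    x$n, x$mean, x$sd, x$bounds[1], x$bounds[2],
    x$p_lower, x$p_upper, x$p_overall,
    if (x$equivalent) "EQUIVALENT" else "not equivalent",
    x$ci90[1], x$ci90[2], x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Equivalence report over a difference table
#'
#' The headline analysis: one pooled TOST per modality over all translation
#' differences (the three translation axes concatenated, mirroring the
#' study's single 3D and single 2D test), plus per-direction translation
#' TOSTs as diagnostics. Rotations are summarized elsewhere but not
#' TOST-tested.
#'
#' @param table a difference table from [dof_differences()]
#' @param low,high,alpha passed to [tost_paired()]
#' @return named list per modality, each with `pooled` (a `tost_result`)
#'   and `per_direction` (list of `tost_result` keyed by RL/PA/IS)
#' @export
equivalence_report <- function(table, low = -1, high = 1, alpha = 0.05) {
  trans <- c("RL", "PA", "IS")
  out <- list()
  for (mod in unique(as.character(table$modality))) {
    g <- table[table$modality == mod & table$direction %in% trans, ]
    if (nrow(g) == 0L) next
    pooled <- tost_paired(g$difference, low, high, alpha)
    per_dir <- lapply(trans, function(d)
      tost_paired(g$difference[g$direction == d], low, high, alpha))
    names(per_dir) <- trans
    out[[mod]] <- list(pooled = pooled, per_direction = per_dir)
  }
  out
}
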