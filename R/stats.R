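#' Two-sided Wilcoxon rank-sum test
#'
#' Implemented from the rank-sum formulas rather than delegated, so that the
#' tie convention is explicit: midranks are used throughout. Small samples
#' (at most `exact_max` distinct rank assignments) are evaluated by complete
#' enumeration of the null distribution of the rank sum conditional on the
#' observed (possibly tied) pooled values; larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric samples (each non-empty).
#' @param exact_max enumeration budget: exact p when
#'   `choose(n_a + n_b, n_a) <= exact_max`.
#' @return list `p` (two-sided), `statistic` (rank sum of `a`), `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 20000) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(p = 1, statistic = sum(rank(pooled)[seq_len(n1)]),
                method = "degenerate"))
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  if (choose(n1 + n2, n1) <= exact_max) {
    cmb <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[cmb], nrow = n1))
    ref <- abs(sums - n1 * (n1 + n2 + 1) / 2)
    obs <- abs(w - n1 * (n1 + n2 + 1) / 2)
    p <- mean(ref >= obs - 1e-9)
    return(list(p = p, statistic = w, method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(p = 1, statistic = w, method = "normal"))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
  list(p = min(1, 2 * pnorm(-abs(z))), statistic = w, method = "normal")
}

#' Kruskal-Wallis test with Dunn's post hoc pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared reference
#' (`df = k - 1`). When the omnibus test is rejected at `alpha`, Dunn's
#' z-tests are run for every pair of groups (unadjusted by default; Holm
#' adjustment by flag); otherwise the pairwise p-values are reported as `NA`
#' (not significant by gating).
#'
#' @param groups list of numeric samples (3 for the intensity comparison).
#' @param alpha gate for running the post hoc tests.
#' @param adjust `"none"` (default) or `"holm"` for the Dunn p-values.
#' @return list `kw_p`, `H`, `pairwise` (data.frame `i`, `j`, `z`, `p`).
#' @export
kruskal_dunn <- function(groups, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 1L) < 1L)) stop("a group is empty")
  k <- length(groups)
  n_i <- vapply(groups, length, 1L)
  n <- sum(n_i)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), times = n_i)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  H <- 12 / (n * (n + 1)) * sum(n_i * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  kw_p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(i = pairs[1, ], j = pairs[2, ], z = NA_real_, p = NA_real_)
  if (kw_p <= alpha) {
    tie_adj <- sum(ties^3 - ties) / (12 * (n - 1))
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      se <- sqrt((n * (n + 1) / 12 - tie_adj) * (1 / n_i[i] + 1 / n_i[j]))
      z <- (rbar[i] - rbar[j]) / se
      pw$z[q] <- z
      pw$p[q] <- min(1, 2 * pnorm(-abs(z)))
    }
    if (adjust == "holm") pw$p <- stats::p.adjust(pw$p, method = "holm")
  }
  list(kw_p = kw_p, H = H, pairwise = pw)
}

#' Map a p-value to significance stars
#'
#' `*`, `**`, `***`, `****` for p at or below 0.05, 0.01, 0.001, 1e-4
#' (the strongest printed grade, "p much below 0.001", is rendered as the
#' numeric cutoff 1e-4); `ns` otherwise or for `NA`.
#'
#' @param p p-value (vectorized).
#' @return character vector of star codes.
#' @export
sig_stars <- function(p) {
  out <- rep("ns", length(p))
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[!is.na(p) & p <= 1e-4] <- "****"
  out
}

#' Significance grid over layers, features and comparisons
#'
#' Reproduces the tabular analysis of evoked-response features: per layer and
#' feature, the diagonal cells compare UP vs DOWN at each stimulation
#' intensity (Wilcoxon rank-sum); the off-diagonal cells compare intensity
#' pairs within the UP state (upper triangle) and within the DOWN state
#' (lower triangle) using Dunn's test gated by a Kruskal-Wallis omnibus test
#' across the three intensities. Direction is the sign of the median
#' difference (first-named group minus second).
#'
#' @param features long data.frame with columns `layer`, `amp_class`,
#'   `state`, and one column per feature named in `feature_cols`.
#' @param feature_cols names of the feature columns to analyze.
#' @param alpha omnibus gate for the Dunn tests.
#' @param adjust Dunn p adjustment, `"none"` or `"holm"`.
#' @return data.frame of cells: `feature`, `layer`, `comparison` (kind),
#'   `pair`, `p`, `stars`, `direction`, `n1`, `n2`.
#' @export
build_sig_table <- function(features, feature_cols, alpha = 0.05,
                            adjust = "none") {
  classes <- c("large", "medium", "small")
  out <- list()
  add <- function(feature, layer, comparison, pair, p, dir, n1, n2) {
    out[[length(out) + 1L]] <<- data.frame(
      feature = feature, layer = layer, comparison = comparison, pair = pair,
      p = p, stars = sig_stars(p), direction = dir, n1 = n1, n2 = n2,
      stringsAsFactors = FALSE)
  }
  med_dir <- function(x, y) {
    if (all(is.na(x)) || all(is.na(y))) return(NA_character_)
    d <- median(x, na.rm = TRUE) - median(y, na.rm = TRUE)
    if (d > 0) "increase" else if (d < 0) "decrease" else "equal"
  }
  for (l in unique(features$layer)) {
    fl <- features[features$layer == l, , drop = FALSE]
    for (f in feature_cols) {
      # diagonal: UP vs DOWN per intensity
      for (cl in classes) {
        xu <- fl[[f]][fl$amp_class == cl & fl$state == "UP"]
        xd <- fl[[f]][fl$amp_class == cl & fl$state == "DOWN"]
        xu <- xu[!is.na(xu)]; xd <- xd[!is.na(xd)]
        if (length(xu) < 1 || length(xd) < 1) {
          warning(sprintf("empty UP/DOWN group for %s/%s/%s; cell rendered ns",
                          f, l, cl))
          add(f, l, "UPvsDOWN", cl, NA_real_, NA_character_,
              length(xu), length(xd))
        } else {
          w <- wilcoxon_rank_sum(xu, xd)
          add(f, l, "UPvsDOWN", cl, w$p, med_dir(xu, xd),
              length(xu), length(xd))
        }
      }
      # off-diagonal: intensity pairs within each state
      for (st in c("UP", "DOWN")) {
        gs <- lapply(classes, function(cl)
          fl[[f]][fl$amp_class == cl & fl$state == st])
        gs <- lapply(gs, function(g) g[!is.na(g)])
        kind <- paste0("intensity@", st)
        if (any(vapply(gs, length, 1L) < 2L)) {
          warning(sprintf("degenerate intensity group for %s/%s/%s; cells rendered ns",
                          f, l, st))
          for (q in list(c(1, 2), c(1, 3), c(2, 3)))
            add(f, l, kind, paste(classes[q], collapse = "-"), NA_real_,
                NA_character_, length(gs[[q[1]]]), length(gs[[q[2]]]))
          next
        }
        kd <- kruskal_dunn(gs, alpha = alpha, adjust = adjust)
        for (q in seq_len(nrow(kd$pairwise))) {
          i <- kd$pairwise$i[q]; j <- kd$pairwise$j[q]
          add(f, l, kind, paste(classes[c(i, j)], collapse = "-"),
              kd$pairwise$p[q], med_dir(gs[[i]], gs[[j]]),
              length(gs[[i]]), length(gs[[j]]))
        }
      }
    }
  }
  do.call(rbind, out)
}
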