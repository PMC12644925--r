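# Independent oracles, deliberately coded with plain loops and their own
# formulas so they share no code path with the package implementation.

# Exhaustive dual-cutoff search over the same candidate grid (midpoints of
# consecutive sorted unique values plus sentinels), with the documented
# conventions: undefined metrics never satisfy a constraint, infinite PLR
# does; selection is lexicographic in (violated constraints, intermediate
# fraction, width, -(PPV+NPV with NA as 0), lower, upper).
oracle_dual_cutoffs <- function(values, labels, min_ppv = 0.9,
                                min_npv = 0.9, min_plr = 5, max_nlr = 0.1) {
  u <- sort(unique(values))
  cand <- if (length(u) == 1) c(u - 1, u + 1) else
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (lo in cand) {
    for (hi in cand) {
      if (lo > hi) next
      a <- sum(labels & values > hi)
      cc <- sum(labels & values < lo)
      b <- sum(labels) - a - cc
      d <- sum(!labels & values > hi)
      f <- sum(!labels & values < lo)
      e <- sum(!labels) - d - f
      np <- a + b + cc; nn <- d + e + f
      ppv <- if (a + d > 0) a / (a + d) else NA_real_
      npv <- if (cc + f > 0) f / (cc + f) else NA_real_
      plr <- if (d > 0) (a / np) / (d / nn) else if (a > 0) Inf else NA_real_
      nlr <- if (f > 0) (cc / np) / (f / nn) else if (cc > 0) Inf else NA_real_
      nviol <- sum(c(
        !(isTRUE(ppv >= min_ppv)),
        !(isTRUE(npv >= min_npv)),
        !(isTRUE(plr > min_plr)),
        !(isTRUE(nlr < max_nlr))
      ))
      key <- c(nviol,
               (b + e) / (np + nn),
               hi - lo,
               -((if (is.na(ppv)) 0 else ppv) +
                   (if (is.na(npv)) 0 else npv)),
               lo, hi)
      if (is.null(best) || oracle_key_less(key, best$key)) {
        best <- list(key = key, lower = lo, upper = hi,
                     feasible = nviol == 0,
                     intermediate_fraction = (b + e) / (np + nn),
                     ppv = ppv, npv = npv, plr = plr, nlr = nlr)
      }
    }
  }
  best
}

oracle_key_less <- function(k1, k2) {
  for (i in seq_along(k1)) {
    if (k1[i] < k2[i]) return(TRUE)
    if (k1[i] > k2[i]) return(FALSE)
  }
  FALSE
}

# Textbook recursive partial correlation: condition on one covariate at a
# time via r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
oracle_partial_corr_recursive <- function(x, y, z1, z2) {
  r <- function(a, b) stats::cor(a, b)
  step <- function(rxy, rxz, ryz) {
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  rxy_1 <- step(r(x, y), r(x, z1), r(y, z1))
  rxw_1 <- step(r(x, z2), r(x, z1), r(z2, z1))
  ryw_1 <- step(r(y, z2), r(y, z1), r(z2, z1))
  step(rxy_1, rxw_1, ryw_1)
}

# Small helper: a two-class score sample with a known gap.
toy_separated <- function() {
  list(values = c(1, 2, 3, 10, 11, 12),
       labels = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
}
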