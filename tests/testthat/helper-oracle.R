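# Independent oracles.
#
# (1) A brute-force 1-minute-grid scan re-implementing the episode
#     rules by exhaustive enumeration over grid points, for records
#     whose sample times all lie on the minute grid. Used to check the
#     interval-algebra implementation exactly (both sides produce
#     endpoints that are sample times or the stay end).
# (2) A generic convex optimizer (box-constrained L-BFGS-B on the
#     positive/negative split) for the elastic-net objective.
# (3) Full-enumeration exact Wilcoxon rank-sum p-values.

# ---- minute-grid episode oracle ----------------------------------------

grid_hold_flags <- function(series, predicate, stay_min) {
  flag <- rep(FALSE, stay_min + 1L) # minutes 0..stay_min
  if (is.null(series) || !length(series$times)) return(flag)
  idx <- as.integer(round(series$times * 60)) + 1L
  ok <- as.logical(predicate(series$values))
  for (k in seq_along(idx)) {
    flag[idx[k]:(stay_min + 1L)] <- ok[k]
  }
  flag
}

grid_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(s = starts[keep] - 1L, e = ends[keep] - 1L) # minute idx
}

# run (minute indices) -> continuous interval [start_h, end_h]
run_to_interval <- function(s, e, stay_min) {
  end_min <- ifelse(e >= stay_min, stay_min, e + 1L)
  data.frame(start_h = s / 60, end_h = end_min / 60)
}

oracle_abnormality <- function(record, config) {
  stay_min <- as.integer(round(record$icu_stay_h * 60))
  flags <- list(
    temperature = grid_hold_flags(record$series[["T"]], function(v)
      v > config$temp_high | v < config$temp_low, stay_min),
    heart_rate = grid_hold_flags(record$series[["HR"]], function(v)
      v > config$hr_thresh, stay_min),
    respiratory_rate = grid_hold_flags(record$series[["RR"]], function(v)
      v > config$rr_thresh, stay_min),
    wbc = grid_hold_flags(record$series[["WBC"]], function(v)
      v > config$wbc_high | v < config$wbc_low, stay_min))
  count <- Reduce(`+`, lapply(flags, as.integer))
  met <- grid_runs(count >= config$min_criteria)
  if (!nrow(met)) return(data.frame(start_h = numeric(),
                                    end_h = numeric()))
  # backtrack each met start through any criterion continuously abnormal
  bt <- vapply(met$s, function(s) {
    best <- s
    for (f in flags) {
      if (f[s + 1L]) { # flagged at the met start
        m <- s
        while (m > 0L && f[m]) m <- m - 1L
        best <- min(best, m)
      }
    }
    best
  }, 0L)
  iv <- run_to_interval(bt, met$e, stay_min)
  iv <- iv[order(iv$start_h), , drop = FALSE]
  # merge gaps < merge_gap_h (strict), in minutes
  gap_min <- as.integer(round(config$merge_gap_h * 60))
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(out)
      if (round((iv$start_h[i] - out$end_h[last]) * 60) < gap_min) {
        out$end_h[last] <- max(out$end_h[last], iv$end_h[i])
      } else {
        out <- rbind(out, iv[i, ])
      }
    }
  }
  # duration must exceed min_episode_h (strict)
  keep <- round((out$end_h - out$start_h) * 60) >
    round(config$min_episode_h * 60)
  out[keep, , drop = FALSE]
}

oracle_hypotension <- function(record, config) {
  stay_min <- as.integer(round(record$icu_stay_h * 60))
  flag <- grid_hold_flags(record$series[["SBP"]], function(v)
    v < config$sbp_thresh, stay_min)
  runs <- grid_runs(flag)
  if (!nrow(runs)) return(data.frame(start_h = numeric(),
                                     end_h = numeric()))
  iv <- run_to_interval(runs$s, runs$e, stay_min)
  keep <- round((iv$end_h - iv$start_h) * 60) >= config$min_hypo_min
  iv[keep, , drop = FALSE]
}

oracle_fluid <- function(fluids, start_h, end_h, config) {
  lo <- start_h - config$fluid_pre_h
  hi <- start_h + (end_h - start_h) / 2
  if (!nrow(fluids)) return(0)
  sum(fluids$volume_ml[fluids$time_h >= lo & fluids$time_h <= hi])
}

oracle_onset <- function(record, sirs, shock) {
  abn <- oracle_abnormality(record, sirs)
  hypo <- oracle_hypotension(record, shock)
  if (nrow(hypo) == 0L) {
    return(list(onset_h = NA_real_, reason = "no_prolonged_hypotension"))
  }
  if (nrow(hypo) == 1L) {
    return(list(onset_h = NA_real_, reason = "single_hypotension_episode"))
  }
  if (nrow(abn) == 0L) {
    return(list(onset_h = NA_real_, reason = "no_sirs"))
  }
  qualified <- vapply(seq_len(nrow(hypo)), function(i) {
    overlap <- any(abn$start_h < hypo$end_h[i] &
                   abn$end_h > hypo$start_h[i])
    overlap && oracle_fluid(record$fluids, hypo$start_h[i],
                            hypo$end_h[i], shock) > shock$fluid_thresh_ml
  }, TRUE)
  if (!any(qualified)) {
    return(list(onset_h = NA_real_, reason = "no_fluid_qualified"))
  }
  list(onset_h = min(hypo$start_h[qualified]), reason = "labeled")
}

# ---- convex-optimizer elastic-net oracle -------------------------------

# population-sd standardization matching the package's internal one
pop_standardize <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  s <- sqrt(colMeans(xc^2))
  sweep(xc, 2, ifelse(s > 0, s, 1), `/`)
}

enet_optim_oracle <- function(xs, yc, lambda, alpha) {
  # minimize (1/2n)||yc - xs b||^2 + lambda(alpha|b|_1 + (1-alpha)/2|b|^2)
  # over b = bp - bm with bp, bm >= 0 (standard smooth reformulation)
  n <- nrow(xs); p <- ncol(xs)
  obj <- function(par) {
    b <- par[1:p] - par[(p + 1):(2 * p)]
    r <- yc - xs %*% b
    0.5 * mean(r^2) + lambda * (alpha * sum(par) +
                                (1 - alpha) / 2 * sum(b^2))
  }
  grad <- function(par) {
    b <- par[1:p] - par[(p + 1):(2 * p)]
    g <- -crossprod(xs, yc - xs %*% b) / n + lambda * (1 - alpha) * b
    c(g + lambda * alpha, -g + lambda * alpha)
  }
  fit <- optim(rep(0, 2 * p), obj, grad, method = "L-BFGS-B",
               lower = 0, control = list(factr = 10, maxit = 2000))
  fit$par[1:p] - fit$par[(p + 1):(2 * p)]
}

orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  m <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(m))
  x <- sqrt(n) * q # mean-zero columns with (1/n) X'X = I
  colnames(x) <- paste0("f", seq_len(p))
  x
}

# ---- exact rank-sum enumeration ----------------------------------------

enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  m <- length(x); N <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) # rank sum of group x
  combs <- utils::combn(N, m)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  center <- m * (N + 1) / 2
  mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
}
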