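# Independent oracles and shared fixtures for the suite.

# Brute-force minimum-cost one-to-one partial assignment with birth/death
# charges: enumerates every assignment, computing the cost from the stated
# formula directly (independent of the solver's cost construction).
brute_force_link_cost <- function(dets_t, dets_t1, gate, w_dist, w_int,
                                  iscale, b) {
  nt <- nrow(dets_t); nt1 <- nrow(dets_t1)
  if (nt == 0L) return(b * nt1)
  if (nt1 == 0L) return(b * nt)
  cost <- matrix(Inf, nt, nt1)
  for (i in seq_len(nt)) for (j in seq_len(nt1)) {
    d <- sqrt((dets_t$x_px[i] - dets_t1$x_px[j])^2 +
              (dets_t$y_px[i] - dets_t1$y_px[j])^2)
    if (d <= gate)
      cost[i, j] <- w_dist * d / gate +
        w_int * abs(dets_t$intensity[i] - dets_t1$intensity[j]) / iscale
  }
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > nt) {
      best <<- min(best, acc + b * sum(!used))
      return(invisible())
    }
    recurse(i + 1L, used, acc + b)          # detection i dies
    for (j in which(!used)) if (is.finite(cost[i, j])) {
      used[j] <- TRUE
      recurse(i + 1L, used, acc + cost[i, j])
      used[j] <- FALSE
    }
    invisible()
  }
  recurse(1L, rep(FALSE, nt1), 0)
  best
}

# Realized total cost of a link_frames() result under the same formula.
realized_link_cost <- function(links, dets_t, dets_t1, gate, w_dist, w_int,
                               iscale, b) {
  tot <- 0
  if (nrow(links) > 0L) for (r in seq_len(nrow(links))) {
    i <- links$i[r]; j <- links$j[r]
    d <- sqrt((dets_t$x_px[i] - dets_t1$x_px[j])^2 +
              (dets_t$y_px[i] - dets_t1$y_px[j])^2)
    tot <- tot + w_dist * d / gate +
      w_int * abs(dets_t$intensity[i] - dets_t1$intensity[j]) / iscale
  }
  tot + b * (nrow(dets_t) - nrow(links)) + b * (nrow(dets_t1) - nrow(links))
}

random_detection_frame <- function(n, span = 20) {
  data.frame(x_px = stats::runif(n, 0, span),
             y_px = stats::runif(n, 0, span),
             intensity = stats::runif(n, 50, 150))
}

# Render a clean frame with Gaussian spots (image-formation oracle shared by
# detection tests).
spot_frame <- function(ny, nx, spots, sigma = 1.5, amplitude = 50,
                       noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(0, ny, nx)
  for (i in seq_len(nrow(spots)))
    f <- endotrack:::add_gaussian_spot(f, spots$x[i], spots$y[i],
                                       sigma, amplitude)
  if (noise_sd > 0) f <- f + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
  f
}

# Shared simulated acquisition at the default high-SNR preset, computed once
# per session and reused by the acceptance blocks.
.sim_cache <- new.env(parent = emptyenv())
default_preset_pipeline <- function() {
  if (is.null(.sim_cache$default)) {
    cfg <- preset_control(seed = 20260929L)
    .sim_cache$default <- run_pipeline(cfg)
  }
  .sim_cache$default
}
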