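# Independent brute-force oracles used across the test files. These stay
# deliberately naive (explicit loops, direct definitions) so they are
# independent of the package's vectorised/compiled implementations.

scd_naive <- function(q) {
  n <- length(q)
  s <- 0
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      s <- s + q[i] * q[j] * sqrt(i - j)
    }
  }
  s / n
}

kappa_naive <- function(q, blob_sizes = c(5, 6)) {
  sigma <- function(qq) {
    fp <- sum(qq > 0) / length(qq)
    fm <- sum(qq < 0) / length(qq)
    if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
  }
  delta <- function(qq, g) {
    sg <- sigma(qq)
    devs <- c()
    for (i in 1:(length(qq) - g + 1)) {
      devs <- c(devs, (sigma(qq[i:(i + g - 1)]) - sg)^2)
    }
    mean(devs)
  }
  qmax <- c(sort(q[q < 0]), q[q == 0], sort(q[q > 0]))
  mean(sapply(blob_sizes, function(g) delta(q, g) / delta(qmax, g)))
}

acf_naive <- function(x, max_lag, subtract_mean) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (subtract_mean) x <- sweep(x, 2, colMeans(x))
  n <- nrow(x)
  raw <- sapply(0:max_lag, function(L) {
    s <- 0
    for (t0 in 1:(n - L)) s <- s + sum(x[t0, ] * x[t0 + L, ])
    s / (n - L)
  })
  raw / raw[1]
}

# wrap a raw bd_run result as a cg_trajectory for analysis helpers
as_traj <- function(res, seq, config) {
  seq <- as_cg_sequence(seq)
  o <- res$obs
  obs <- tibble::tibble(
    run = 1L, step = o[, 1], time = o[, 1] * config$dt,
    re_x = o[, 2], re_y = o[, 3], re_z = o[, 4],
    re = sqrt(o[, 2]^2 + o[, 3]^2 + o[, 4]^2), rg2 = o[, 5]
  )
  structure(list(frames = list(res$frames), obs = obs,
                 final = list(res$final), n_reject = res$n_reject,
                 meta = list(sequence = seq, name = attr(seq, "name"),
                             config = config, sub_seeds = NA)),
            class = "cg_trajectory")
}

labels_of <- function(s) as.vector(unclass(s))
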