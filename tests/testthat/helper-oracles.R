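# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately written in the most literal way possible (loops, normal
# equations, textbook algorithm transcriptions) and shares no code with the
# package internals it checks.

make_spectra_tbl <- function(m, wl = NULL) {
  m <- as.matrix(m)
  wl <- wl %||% seq(400, by = 2, length.out = ncol(m))
  new_spectra(m, wl, sprintf("S%03d", seq_len(nrow(m))))
}

rand_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Literal transcription of the gap-segment derivative definition: boxcar
# smoothing, centered gap differences applied d times, boxcar again, all with
# explicit index loops and valid-region trimming.
gap_deriv_oracle <- function(x, d, g, s1, s2) {
  norm_seg <- function(s) if (s <= 1) 1L else if (s %% 2 == 0) s + 1L else s
  smooth <- function(v, s) {
    if (s <= 1) return(v)
    h <- (s - 1) / 2
    out <- numeric(0)
    for (i in (1 + h):(length(v) - h)) out <- c(out, mean(v[(i - h):(i + h)]))
    out
  }
  diff1 <- function(v, g) {
    hl <- floor(g / 2)
    hr <- g - hl
    out <- numeric(0)
    for (i in (1 + hl):(length(v) - hr)) out <- c(out, v[i + hr] - v[i - hl])
    out
  }
  v <- smooth(x, norm_seg(s1))
  if (d > 0) for (j in seq_len(d)) v <- diff1(v, g)
  smooth(v, norm_seg(s2))
}

# Polynomial detrend via explicit normal equations (QR-free route).
detrend_oracle <- function(x, wl, degree) {
  z <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
  v <- outer(z, 0:degree, `^`)
  beta <- solve(t(v) %*% v, t(v) %*% x)
  drop(x - v %*% beta)
}

# Textbook NIPALS PLS1: mean-center, extract factors by iterated deflation,
# coefficients at rank r from B = W (P'W)^-1 q. Used as the independent
# reference for fit_pls1(modified = FALSE).
nipals_oracle <- function(x, y, max_rank) {
  xc <- colMeans(x)
  yc <- mean(y)
  e <- sweep(x, 2, xc)
  f <- y - yc
  w_l <- p_l <- list()
  q_l <- numeric(0)
  for (a in seq_len(max_rank)) {
    w <- drop(t(e) %*% f)
    w <- w / sqrt(sum(w^2))
    t_ <- drop(e %*% w)
    p <- drop(t(e) %*% t_) / sum(t_^2)
    q <- sum(f * t_) / sum(t_^2)
    e <- e - outer(t_, p)
    f <- f - q * t_
    w_l[[a]] <- w
    p_l[[a]] <- p
    q_l[a] <- q
  }
  coefs <- function(r) {
    w_m <- do.call(cbind, w_l[1:r])
    p_m <- do.call(cbind, p_l[1:r])
    drop(w_m %*% solve(t(p_m) %*% w_m, q_l[1:r]))
  }
  predict_at <- function(xnew, r) {
    drop(sweep(xnew, 2, xc) %*% coefs(r)) + yc
  }
  list(coefs = coefs, predict = predict_at, x_center = xc, y_center = yc)
}

# Closed-form truncated-normal mean (the distribution the generator samples).
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Cross-validated mean-only SECV: direct formula from held-out group means.
secv0_oracle <- function(y, assignment) {
  press <- 0
  for (g in unique(assignment)) {
    hold <- assignment == g
    press <- press + sum((y[hold] - mean(y[!hold]))^2)
  }
  sqrt(press / length(y))
}
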