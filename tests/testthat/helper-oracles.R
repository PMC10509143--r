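# Independent elementwise oracles for the error metrics and colour moments,
# plus a constructor for published metric rows.

mae_oracle <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(p[i] - y[i])
  s / length(y)
}

mape_oracle <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs((p[i] - y[i]) / y[i])
  100 * s / length(y)
}

r2_oracle <- function(y, p) {
  ybar <- mean(y)
  num <- 0
  den <- 0
  for (i in seq_along(y)) {
    num <- num + (y[i] - p[i])^2
    den <- den + (y[i] - ybar)^2
  }
  1 - num / den
}

moments_oracle <- function(v) {
  n <- length(v)
  mea <- sum(v) / n
  s2 <- 0
  s3 <- 0
  for (x in v) {
    s2 <- s2 + (x - mea)^2
    s3 <- s3 + (x - mea)^3
  }
  va <- sqrt(s2 / n)
  m3 <- s3 / n
  c(mea = mea, var = va, ske = sign(m3) * abs(m3)^(1 / 3))
}

metric_set_from <- function(mae, mape, r2, n = NA_integer_) {
  structure(list(mae = mae, mape = mape, r2 = r2, n = n),
            class = "metric_set")
}
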