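# shared fixtures, all generated in code

random_states <- function(n, dim, seed, scale = 2) {
  set.seed(seed)
  matrix(runif(n * dim, -scale, scale), n, dim)
}

# brute-force ordered-pair sum of squared distances (independent of the
# crossprod-based computation inside sync_error)
brute_pair_sum <- function(X) {
  n <- nrow(X)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + sum((X[i, ] - X[j, ])^2)
    }
  }
  s
}

# FN equilibrium at zero input by an independent scalar root find:
# w = (a - v)/b reduces the fixed point to one equation in v.
fn_equilibrium <- function(params = fn_params()) {
  g <- function(v) v + (params$a - v) / params$b - v^3 / 3
  v <- stats::uniroot(g, c(-3, 3), tol = 1e-14)$root
  c(v, (params$a - v) / params$b)
}

# independent expanded-polynomial evaluation of the Hindmarsh-Rose drift
# (plain term-by-term sums, no shared code with hr_drift)
hr_poly_oracle <- function(s, input = 0, p = hr_params()) {
  x <- s[1]; y <- s[2]; z <- s[3]
  c(y + (-p$a) * x * x * x + p$b * x * x + (-1) * z + input,
    p$c + (-p$d) * x * x + (-1) * y,
    p$r * p$s * x + (-p$r * p$s) * p$x_r + (-p$r) * z)
}

fn_test_model <- function() fn_model()

quiet_bound <- function(expr) suppressWarnings(expr)
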