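# internal helpers shared across modules

# sin(x)/x with the x -> 0 limit
sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

# Wald-Wolfowitz runs test on the signs of `x` (usually fit residuals).
# Returns the one-sided p-value for "too few runs", i.e. systematic trend.
# Exact combinatorial distribution up to n = 40; normal approximation with
# continuity correction beyond.
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n <- length(s)
  if (n < 2) return(1)
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(1)
  runs <- 1 + sum(s[-1] != s[-n])
  if (n <= 40) {
    # P(R = r) for r runs among n1 positive and n2 negative signs
    p_r <- function(r) {
      if (r %% 2 == 0) {
        k <- r / 2
        2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
      } else {
        k <- (r - 1) / 2
        choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
          choose(n1 - 1, k - 1) * choose(n2 - 1, k)
      }
    }
    return(sum(vapply(2:runs, p_r, numeric(1))) / choose(n, n1))
  }
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  stats::pnorm((runs - mu + 0.5) / sqrt(v))
}

# rotation matrix for angle `theta` (radians) about unit axis `u` (Rodrigues)
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# uniform random unit vector
random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# radius of gyration of a point set, optionally weighted
rg_from_coords <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  w <- weights / sum(weights)
  ctr <- colSums(xyz * w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2))
}

# run `expr` with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

element_property <- function(elements, column, table = element_table) {
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  table[[column]][idx]
}
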