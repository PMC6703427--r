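# Exact rational arithmetic on integer numerator/denominator pairs.
#
# Reaction balancing must be exact: element and charge conservation are
# asserted as identities, not to within floating-point tolerance. The
# matrices involved are tiny (a handful of elements by a handful of
# species) with small integer entries, so numerators and denominators
# stay far below 2^53 and plain doubles carry them exactly.

q_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

# canonical form: den > 0, gcd(num, den) = 1, 0 is 0/1
q_reduce <- function(n, d) {
  if (d == 0) stop("rational with zero denominator", call. = FALSE)
  if (n == 0) return(c(0, 1))
  if (d < 0) { n <- -n; d <- -d }
  g <- q_gcd(n, d)
  c(n / g, d / g)
}

q_add <- function(x, y) q_reduce(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
q_sub <- function(x, y) q_reduce(x[1] * y[2] - y[1] * x[2], x[2] * y[2])
q_mul <- function(x, y) q_reduce(x[1] * y[1], x[2] * y[2])
q_div <- function(x, y) {
  if (y[1] == 0) stop("division by zero rational", call. = FALSE)
  q_reduce(x[1] * y[2], x[2] * y[1])
}

#' @noRd
q_from_int <- function(k) c(k, 1)

# recover the exact small rational behind a double (continued fractions);
# reaction coefficients in this package are integers or simple fractions,
# so this is exact in practice
q_from_numeric <- function(x, max_den = 1e6, tol = 1e-9) {
  if (abs(x - round(x)) < tol) return(q_reduce(round(x), 1))
  sgn <- if (x < 0) -1 else 1
  x <- abs(x)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0
  y <- x
  for (i in 1:64) {
    a <- floor(y)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(h / k - x) < tol) break
    frac <- y - a
    if (frac < 1e-15) break
    y <- 1 / frac
  }
  q_reduce(sgn * h1, k1)
}

q_as_numeric <- function(x) x[1] / x[2]

q_format <- function(x) {
  if (x[2] == 1) format(x[1], scientific = FALSE)
  else paste0(format(x[1], scientific = FALSE), "/", format(x[2], scientific = FALSE))
}

q_parse <- function(s) {
  s <- trimws(s)
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed rational string: ", s, call. = FALSE)
    q_reduce(as.numeric(parts[1]), as.numeric(parts[2]))
  } else {
    q_reduce(as.numeric(s), 1)
  }
}

# Solve A x = b exactly over the rationals, where A is an integer matrix
# (m x k) and b a rational right-hand side (list of length m).
# Returns list(status, x) where status is one of "unique", "underdetermined",
# "inconsistent"; x is a list of rationals when unique.
q_solve <- function(A, b) {
  m <- nrow(A); k <- ncol(A)
  # augmented rational matrix as list-of-rows of rational pairs
  M <- vector("list", m)
  for (i in seq_len(m)) {
    row <- vector("list", k + 1)
    for (j in seq_len(k)) row[[j]] <- q_from_int(A[i, j])
    row[[k + 1]] <- b[[i]]
    M[[i]] <- row
  }
  pivot_col <- integer(0)
  r <- 1
  for (col in seq_len(k)) {
    piv <- 0
    for (i in r:m) if (i <= m && M[[i]][[col]][1] != 0) { piv <- i; break }
    if (piv == 0) next
    tmp <- M[[r]]; M[[r]] <- M[[piv]]; M[[piv]] <- tmp
    pv <- M[[r]][[col]]
    for (j in seq_len(k + 1)) M[[r]][[j]] <- q_div(M[[r]][[j]], pv)
    for (i in seq_len(m)) {
      if (i == r) next
      f <- M[[i]][[col]]
      if (f[1] == 0) next
      for (j in seq_len(k + 1)) {
        M[[i]][[j]] <- q_sub(M[[i]][[j]], q_mul(f, M[[r]][[j]]))
      }
    }
    pivot_col <- c(pivot_col, col)
    r <- r + 1
    if (r > m) break
  }
  # inconsistency: a zero row with nonzero rhs
  for (i in seq_len(m)) {
    all_zero <- all(vapply(seq_len(k), function(j) M[[i]][[j]][1] == 0, logical(1)))
    if (all_zero && M[[i]][[k + 1]][1] != 0) {
      return(list(status = "inconsistent"))
    }
  }
  if (length(pivot_col) < k) return(list(status = "underdetermined"))
  x <- vector("list", k)
  for (idx in seq_along(pivot_col)) x[[pivot_col[idx]]] <- M[[idx]][[k + 1]]
  list(status = "unique", x = x)
}
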