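#' Site frequency spectrum objects
#'
#' An `sfs` object stores a site frequency spectrum together with the haploid
#' sample size `n`, its folding state and the sequence length `L` (in bases).
#' Unfolded spectra hold the counts of segregating sites with derived-allele
#' count `i = 1..n-1` (xi_i); folded spectra hold counts by minor-allele count
#' `i = 1..floor(n/2)` (eta_i). Counts are stored as reals so that observed
#' spectra and expected (mean) spectra share one representation; use
#' `integral = TRUE` to insist on integer counts for observed data.
#'
#' @param counts numeric vector of non-negative class counts, 1-based in the
#'   allele count `i`.
#' @param n haploid sample size (integer >= 2).
#' @param folded logical; is `counts` indexed by minor-allele count?
#' @param L sequence length in bases (positive).
#' @param integral if `TRUE`, require all counts to be whole numbers.
#' @return An object of class `sfs`: a list with elements `counts`, `n`,
#'   `folded`, `L`.
#' @examples
#' sfs(c(3, 2, 1), n = 4, L = 100)
#' @export
sfs <- function(counts, n, folded = FALSE, L = 1L, integral = FALSE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("'n' must be a single integer >= 2")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("'counts' must be a finite numeric vector")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  len <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != len)
    stop(sprintf("'counts' must have length %d for n = %d (%s)",
                 len, n, if (folded) "folded" else "unfolded"))
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("'L' must be a positive sequence length")
  if (integral && any(abs(counts - round(counts)) > 1e-8))
    stop("observed counts must be whole numbers when integral = TRUE")
  structure(list(counts = as.numeric(counts), n = n,
                 folded = isTRUE(folded), L = as.numeric(L)),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s site frequency spectrum: n = %d, L = %g, S = %g\n",
              if (x$folded) "Folded" else "Unfolded", x$n, x$L,
              sum(x$counts)))
  print(stats::setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Total number of segregating sites
#'
#' @param spec an [sfs] object.
#' @return Sum of all class counts.
#' @export
segregating_sites <- function(spec) {
  stopifnot(inherits(spec, "sfs"))
  sum(spec$counts)
}

#' Harmonic number a_n
#'
#' The factor `a_n = sum_{j=1}^{n-1} 1/j` that normalises the Watterson
#' estimator; asymptotically `log(n) + gamma + O(1/n)`.
#'
#' @param n haploid sample size (integer >= 2), possibly vectorised.
#' @return `a_n` for each element of `n`.
#' @examples
#' harmonic_number(4)  # 1 + 1/2 + 1/3
#' @export
harmonic_number <- function(n) {
  if (any(n < 2)) stop("'n' must be >= 2")
  vapply(n, function(m) sum(1 / seq_len(m - 1L)), numeric(1))
}

#' Expected spectrum under the standard neutral model
#'
#' Mean SFS of the standard Wright-Fisher neutral model: `E(xi_i) = theta*L/i`
#' unfolded, and `E(eta_i) = theta*L*n / (i*(n-i)*(1 + delta_{i,n-i}))`
#' folded, where `theta` is the population-scaled mutation rate per base.
#'
#' @param n haploid sample size.
#' @param theta scaled mutation rate per base (>= 0).
#' @param L sequence length in bases.
#' @param folded return the folded mean spectrum?
#' @return An [sfs] object holding the expected class counts.
#' @examples
#' null_mean_spectrum(4, theta = 1, L = 1)$counts  # 1, 1/2, 1/3
#' @export
null_mean_spectrum <- function(n, theta, L = 1, folded = FALSE) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (theta < 0) stop("'theta' must be non-negative")
  if (folded) {
    i <- seq_len(n %/% 2L)
    counts <- theta * L * n / (i * (n - i) * (1 + as.numeric(i == n - i)))
  } else {
    i <- seq_len(n - 1L)
    counts <- theta * L / i
  }
  sfs(counts, n = n, folded = folded, L = L)
}

#' Null mean spectrum shape
#'
#' The per-unit-`theta*L` shape of the neutral mean spectrum: `1/i` unfolded,
#' `n/(i(n-i)(1+delta_{i,n-i}))` folded.
#'
#' @inheritParams null_mean_spectrum
#' @return Numeric vector.
#' @export
null_shape <- function(n, folded = FALSE) {
  null_mean_spectrum(n, theta = 1, L = 1, folded = folded)$counts
}

#' Fold an unfolded spectrum
#'
#' Collapses derived-allele classes into minor-allele classes:
#' `eta_i = xi_i + xi_{n-i}` for `i < n/2` and `eta_{n/2} = xi_{n/2}` when `n`
#' is even. The total number of segregating sites is preserved.
#'
#' @param spec an unfolded [sfs] object.
#' @return A folded [sfs] object.
#' @examples
#' fold_sfs(sfs(c(3, 2, 1), n = 4))$counts  # 4, 2
#' @export
fold_sfs <- function(spec) {
  stopifnot(inherits(spec, "sfs"))
  if (spec$folded) stop("spectrum is already folded")
  n <- spec$n
  xi <- spec$counts
  half <- n %/% 2L
  eta <- vapply(seq_len(half), function(i) {
    if (i == n - i) xi[i] else xi[i] + xi[n - i]
  }, numeric(1))
  sfs(eta, n = n, folded = TRUE, L = spec$L)
}

#' Linear unbiased estimator of theta from a spectrum
#'
#' Given normalised weights `omega_i` (summing to 1), computes the estimator
#' `theta_hat = (1/L) * sum_i i * omega_i * xi_i` per base. Applied to the
#' expected neutral spectrum it returns `theta` exactly, for any valid weights.
#'
#' @param spec an [sfs] object.
#' @param omega numeric weight vector matching the spectrum classes and
#'   summing to 1 (relative tolerance `1e-9`).
#' @return Estimated `theta` per base.
#' @examples
#' # Watterson: omega_i proportional to 1/i gives S / (a_n * L)
#' s <- sfs(c(2, 1, 0), n = 4, L = 10)
#' theta_estimator(s, watterson_weights(4))
#' @export
theta_estimator <- function(spec, omega) {
  stopifnot(inherits(spec, "sfs"))
  if (length(omega) != length(spec$counts))
    stop("weight vector length does not match the spectrum")
  if (abs(sum(omega) - 1) > 1e-9 * max(1, sum(abs(omega))))
    stop("weights must be normalised to sum to 1")
  i <- seq_along(spec$counts)
  sum(i * omega * spec$counts) / spec$L
}

#' Read and write SFS tables
#'
#' Plain-text TSV representation: a header line `#n=<n> folded=<0|1> L=<L>`
#' followed by two tab-separated columns `i` and `count`. Reading and writing
#' round-trip exactly.
#'
#' @param spec an [sfs] object.
#' @param path file path.
#' @return `write_sfs` returns `path` invisibly; `read_sfs` returns an [sfs].
#' @export
write_sfs <- function(spec, path) {
  stopifnot(inherits(spec, "sfs"))
  header <- sprintf("#n=%d folded=%d L=%s", spec$n,
                    as.integer(spec$folded), format(spec$L, digits = 17))
  lines <- c(header, sprintf("%d\t%s", seq_along(spec$counts),
                             format(spec$counts, digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("missing SFS header line '#n=<n> folded=<0|1> L=<L>'")
  hdr <- lines[1]
  get_field <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, "=[^ ]+"), hdr))
    if (!length(m)) stop(sprintf("header field '%s' missing", name))
    as.numeric(sub(paste0(name, "="), "", m))
  }
  n <- get_field("#n"); folded <- get_field("folded"); L <- get_field("L")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  idx <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  val <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  counts <- numeric(max(idx))
  counts[idx] <- val
  sfs(counts, n = n, folded = folded == 1, L = L)
}
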