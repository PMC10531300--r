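#' Tally a site frequency spectrum from a VCF
#'
#' Counts biallelic SNVs into derived-allele classes (unfolded, using an
#' ancestral-allele INFO tag, `AA` by default) or minor-allele classes
#' (folded). Diploid genotypes contribute two haploid observations; phasing
#' is irrelevant for allele counts. Sites are skipped (and counted) when they
#' are not biallelic SNVs, have missing genotypes, do not show exactly `n`
#' called alleles, are monomorphic in the sample, or (unfolded) have an
#' ancestral allele that matches neither REF nor ALT.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param n expected haploid sample count per site.
#' @param ancestral INFO tag naming the ancestral allele.
#' @param folded tally minor-allele counts instead (no ancestral tag needed).
#' @param L sequence length to attach to the spectrum.
#' @return An [sfs] object with attribute `skipped` (named counts of skipped
#'   sites by reason).
#' @export
vcf_to_sfs <- function(path, n, ancestral = "AA", folded = FALSE, L = 1) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcf_to_sfs needs the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- numeric(if (folded) n %/% 2L else n - 1L)
  skipped <- c(not_biallelic_snv = 0L, missing_genotypes = 0L,
               monomorphic = 0L, bad_ancestral = 0L)
  info_field <- function(info, tag) {
    if (is.na(info)) return(NA_character_)
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]+"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", tag, "="), "", m)
  }
  for (k in seq_len(nrow(fix))) {
    ref <- fix[k, "REF"]; alt <- fix[k, "ALT"]
    if (is.na(alt) || nchar(ref) != 1L || nchar(alt) != 1L ||
        grepl(",", alt, fixed = TRUE)) {
      skipped["not_biallelic_snv"] <- skipped["not_biallelic_snv"] + 1L
      next
    }
    g <- gt[k, ]
    alleles <- unlist(strsplit(g[!is.na(g)], "[/|]"))
    if (any(is.na(g)) || any(alleles == ".") || length(alleles) != n) {
      skipped["missing_genotypes"] <- skipped["missing_genotypes"] + 1L
      next
    }
    nalt <- sum(alleles == "1")
    if (nalt == 0L || nalt == n) {
      skipped["monomorphic"] <- skipped["monomorphic"] + 1L
      next
    }
    if (folded) {
      i <- min(nalt, n - nalt)
    } else {
      aa <- toupper(info_field(fix[k, "INFO"], ancestral))
      if (is.na(aa) || !(aa %in% c(ref, alt))) {
        skipped["bad_ancestral"] <- skipped["bad_ancestral"] + 1L
        next
      }
      i <- if (aa == ref) nalt else n - nalt
    }
    counts[i] <- counts[i] + 1
  }
  if (sum(counts) == 0 && all(skipped >= 0) && nrow(fix) > 0 &&
      sum(skipped) == nrow(fix))
    stop("no usable sites in the VCF")
  out <- sfs(counts, n = n, folded = folded, L = L)
  attr(out, "skipped") <- skipped
  out
}

#' Serialise a polynomial test to JSON
#'
#' Round-trips the multiset coefficients, the constant term, the centring
#' class and the moment model, so that stored tests evaluate identically
#' after reloading.
#'
#' @param test a [polynomial_test].
#' @return A JSON string.
#' @export
polynomial_to_json <- function(test) {
  stopifnot(inherits(test, "polynomial_test"))
  jsonlite::toJSON(list(
    multisets = lapply(test$multisets, identity),
    coef = test$coef, gamma = test$gamma, centring = test$centring,
    name = test$name,
    model = list(n = test$model$n, theta = test$model$theta,
                 L = test$model$L, folded = test$model$folded,
                 xibar = test$model$xibar)),
    auto_unbox = TRUE, digits = I(17))
}

#' @rdname polynomial_to_json
#' @param json a JSON string from `polynomial_to_json`.
#' @export
polynomial_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  model <- moment_model(x$model$n, x$model$theta, x$model$L,
                        xibar = x$model$xibar, folded = x$model$folded)
  ms <- if (is.matrix(x$multisets)) {
    lapply(seq_len(nrow(x$multisets)), function(r) as.integer(x$multisets[r, ]))
  } else {
    lapply(x$multisets, as.integer)
  }
  polynomial_test(ms, x$coef, x$gamma, x$centring, model, name = x$name)
}

#' Evaluate a set of tests on one spectrum
#'
#' Convenience wrapper producing a tidy table of normalised statistics.
#'
#' @param tests named list of test objects.
#' @param spec an [sfs].
#' @return Data frame with columns `test` and `statistic`.
#' @export
evaluate_tests <- function(tests, spec) {
  data.frame(test = names(tests),
             statistic = vapply(tests, function(t) evaluate_any(t, spec),
                                numeric(1)),
             row.names = NULL)
}
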