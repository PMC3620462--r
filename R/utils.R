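#' @keywords internal
"_PACKAGE"

# Shared conventions:
#  * internal site keys are (contig, 1-based position); BED/bedGraph on disk
#    are 0-based half-open, converted at the boundary
#  * zygosity labels "HOM"/"HET"; "ABSENT" marks a platform without a call
#  * percentages are kept as exact ratios internally; rounding (half away
#    from zero) happens only in reporting helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Reporting rounding rule used for every printed percentage: ties go away
#' from zero (1.675 -> 1.68), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percentage n/d * 100 rounded to 2 dp; NA on zero denominator
pct_of <- function(n, d, digits = 2) {
  ifelse(d > 0, round_half_up(100 * n / d, digits), NA_real_)
}

site_key <- function(contig, pos) {
  if (length(contig) == 0) return(character(0))
  paste0(contig, ":", pos)
}

# Derive a sub-seed for an output role so that adding one output does not
# perturb the RNG stream of the others. Kept well below 2^31.
role_seed <- function(seed, role) {
  offsets <- c(
    reference = 1L, truth = 2L, chip = 3L, mq_mask = 4L,
    p1_depth = 11L, p1_calls = 12L, p1_pileup = 13L,
    p2_depth = 21L, p2_calls = 22L, p2_pileup = 23L,
    suppress_p1 = 31L, suppress_p2 = 32L
  )
  if (!role %in% names(offsets)) stop("unknown RNG role: ", role)
  (as.integer(seed) %% 2000003L) * 1000L + offsets[[role]]
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate that all inputs use exactly the same contig names (no aliasing).
check_contigs <- function(...) {
  sets <- list(...)
  ref <- sort(unique(sets[[1]]))
  for (i in seq_along(sets)[-1]) {
    s <- sort(unique(sets[[i]]))
    bad <- c(setdiff(s, ref), setdiff(ref, s))
    if (length(bad))
      stop("contig names do not match across inputs: ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
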