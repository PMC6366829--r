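#' @keywords internal
"_PACKAGE"

#' @importFrom stats dbinom median rbinom rpois setNames
#' @importFrom utils read.table write.table
NULL

# Autosomes the pipeline reasons over. Sex chromosomes are out of scope:
# their contribution to total chromosome counts enters via config.
AUTOSOMES <- 1:22

# Chromosomes retained disomic in the hyperhaploid samples studied here
# (the hyperdiploidy-trisomy set plus chromosome 18).
DEFAULT_RETAINED_SET <- c(3L, 5L, 7L, 9L, 11L, 15L, 18L, 19L, 21L)

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream, so every seeded operation is a pure function of its arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Normalize chromosome labels: accept "chr1"/"1", return integer 1..22.
# Sex chromosomes are rejected -- all karyotype math here is autosome-only.
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  if (any(toupper(x) %in% c("X", "Y"))) {
    stop("sex chromosomes are not supported; supply autosomes 1-22 only",
         call. = FALSE)
  }
  out <- suppressWarnings(as.integer(x))
  bad <- is.na(out) | out < 1L | out > 22L
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

check_fraction <- function(x, name, lower = 0, upper = 1,
                           lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single number", call. = FALSE)
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop("`", name, "` must be in ", if (lower_open) "(" else "[", lower,
         ", ", upper, if (upper_open) ")" else "]", ", got ", x,
         call. = FALSE)
  }
  invisible(x)
}

# Round half away from zero (so 1.5 -> 2, 2.5 -> 3); base round() rounds
# half to even, which would make copy-number ties depend on parity.
round_half_up <- function(x) floor(x + 0.5)
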