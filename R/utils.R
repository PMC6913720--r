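# Internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-normal draws by rejection; mean/sd may be vectors of length n.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# Coerce a manifest row / named list with sex, mass_kg, height_m, age_yr
# into a gp_subject.
as_gp_subject <- function(x) {
  if (inherits(x, "gp_subject")) return(x)
  subject(as.character(x$sex), as.numeric(x$mass_kg),
          as.numeric(x$height_m), as.numeric(x$age_yr))
}
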