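# internal helpers

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

# Noiseless synthetic series are an intended input; keep summary.lm quiet
# about exactly collinear fits while letting other warnings through.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Write `lines` (or a writer function) to `path` atomically: temp file in the
# same directory, then rename, so a failed producer leaves no partial output.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move temporary file onto %s", path)
  ok <- TRUE
  invisible(path)
}

# Stable fingerprint of an R configuration object (md5 of its deparse).
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = c("exact")), tmp)
  unname(tools::md5sum(tmp))
}
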