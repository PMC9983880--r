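# Internal helpers shared across modules.

#' @importFrom stats plogis quantile rnorm runif rbinom sd var cor median
#'   complete.cases predict coef setNames lm residuals
#' @importFrom utils head read.csv write.csv packageVersion
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators never perturb user code.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Run-log messages; silent unless options(kinoviab.verbose = TRUE).
.log <- function(...) {
  if (isTRUE(getOption("kinoviab.verbose", FALSE))) {
    message("[kinoviab] ", sprintf(...))
  }
  invisible(NULL)
}

# Canonical key for a molar concentration: exact decimal matching after
# canonicalization, avoiding float-tolerance ambiguity.
.doseKey <- function(x) sprintf("%.6e", x)

# Match record concentrations against a dose grid; -1 where absent.
.doseIndex <- function(x, grid) {
  idx <- match(.doseKey(x), .doseKey(grid))
  idx[is.na(idx)] <- -1L
  idx
}

.assertCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= 1", name), call. = FALSE)
  }
  invisible(TRUE)
}

.assertRate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic content hash used by the pipeline manifests.
.hashObject <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

.hashFiles <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(paths)
  as.list(h)
}
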