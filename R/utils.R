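## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kf <- function(fmt, ..., class = "kfibermesh_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "kfibermesh_error")))
}

assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_kf("`%s` must be a single non-missing number", name)
  }
  if (finite && !is.finite(x)) stop_kf("`%s` must be finite", name)
  if (positive && x <= 0) stop_kf("`%s` must be > 0", name)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Stage- and fiber-level randomness is driven by sub-seeds derived
#' deterministically from one master seed, so that per-fiber results do not
#' depend on evaluation order. The derivation hashes the (seed, tag) pair into
#' a 31-bit integer.
#'
#' @param seed Master integer seed.
#' @param tag Character or integer tag naming the consumer (stage, fiber id).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, tag) {
  assert_scalar_num(seed, "seed")
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), "/", paste(tag, collapse = "/")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## Evaluate `code` under a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

## Euclidean distance matrix for an n x 2 (or n x 3) coordinate matrix.
dist_matrix <- function(xy) {
  as.matrix(stats::dist(xy))
}

## Deterministic JSON canonicalisation used by report writing.
write_json_canonical <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          null = "null", na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

## md5 of a canonical serialisation; used for config provenance.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  write_json_canonical(x, tf)
  unname(tools::md5sum(tf))
}
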