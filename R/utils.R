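# Internal helpers shared across modules.

MUSCLES <- c("ED", "PL", "FCU", "ECR")
CLASS_IDS <- 1:15

# Gesture-class groupings used throughout the pipeline.
PINCH_CLASSES <- c(5:8, 12:15)
GRASP_CLASSES <- c(2L, 9L)
RADIAL_CLASSES <- c(3L, 10L)
ULNAR_CLASSES <- c(4L, 11L)
FORCE_CLASSES <- c(GRASP_CLASSES, PINCH_CLASSES) # drive the force sensor
TORQUE_CLASSES <- c(RADIAL_CLASSES, ULNAR_CLASSES) # drive the torque sensor

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed and index terms,
# kept inside the 32-bit integer range R requires.
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 7919 + 1) %% 2147483647
  }
  as.integer(x)
}

# Largest-remainder allocation of `total` across groups proportional to
# `weights`; deterministic ties broken by group order.
allocate_proportional <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    rem <- exact - base
    top <- order(-rem, seq_along(rem))[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
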