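#' Muscle activation matrix for the 15 gesture classes
#'
#' Builds the 4 x 15 matrix of normalized activation levels (in \[0, 1\])
#' that the simulator uses to scale each muscle's amplitude envelope while
#' a given gesture class is active. Rows are the recorded forearm muscles
#' (ED, PL, FCU, ECR), columns the gesture classes 1-15 (rest; grasp,
#' radial/ulnar deviation and four finger pinches in pronation; the same
#' seven gestures in supination).
#'
#' The base pattern encodes the muscles' functional anatomy: FCU (a wrist
#' flexor assisting ulnar deviation) is the dominant muscle for ulnar
#' deviation, ECR (a wrist extensor and radial abductor) for radial
#' deviation, and ED/PL carry most of the grasp and finger-pinch activity.
#' Adjacent finger pinches — middle vs ring, in either arm position — are
#' deliberately the closest pair of columns: ring-finger activity is
#' strongly coupled to its neighbours, which is the confusion structure
#' observed in real forearm sEMG.
#'
#' `profile$separability` shrinks all non-rest columns toward their mean
#' pattern, so lower-separability subjects produce gestures that are
#' harder to tell apart; pairwise column distances scale linearly with it.
#'
#' @param profile A [subject_profile()].
#' @param jitter_sd Standard deviation of subject-specific Gaussian jitter
#'   added to the base pattern before the separability scaling (0 disables).
#' @param seed Integer seed for the jitter; `NULL` (default) disables jitter
#'   so the matrix is a pure function of the profile.
#' @return A `semg_activation` matrix (4 x 15) with muscle rownames and
#'   class-id colnames; the `separability` attribute records the scaling.
#' @export
make_activation_matrix <- function(profile, jitter_sd = 0.006, seed = NULL) {
  stopifnot(inherits(profile, "semg_profile"))
  base <- base_activation_matrix()
  if (!is.null(seed) && jitter_sd > 0) {
    jit <- with_seed(seed, matrix(stats::rnorm(4 * 14, sd = jitter_sd), 4, 14))
    base[, 2:15] <- pmin(1, pmax(0.02, base[, 2:15] + jit))
  }
  s <- profile$separability
  centre <- rowMeans(base[, 2:15])
  base[, 2:15] <- centre + s * (base[, 2:15] - centre)
  base[, 2:15] <- pmin(1, pmax(0, base[, 2:15]))
  structure(base, separability = s, class = c("semg_activation", class(base)))
}

# Base activation pattern at separability 1. Columns: class 1 = rest (all
# zero); 2-8 pronation (grasp, radial, ulnar, pinch index/middle/ring/
# little); 9-15 the supination counterparts. The pinch columns lie on a
# gradient with the middle-ring spacing smallest.
base_activation_matrix <- function() {
  m <- matrix(
    c(
      # ED    PL    FCU   ECR
      0.00, 0.00, 0.00, 0.00, # 1  rest
      0.80, 0.60, 0.50, 0.55, # 2  grasp (pronation)
      0.35, 0.15, 0.15, 0.85, # 3  radial deviation (pronation)
      0.25, 0.45, 0.85, 0.15, # 4  ulnar deviation (pronation)
      0.45, 0.55, 0.15, 0.45, # 5  pinch index (pronation)
      0.55, 0.42, 0.22, 0.35, # 6  pinch middle (pronation)
      0.62, 0.31, 0.30, 0.26, # 7  pinch ring (pronation)
      0.50, 0.20, 0.42, 0.18, # 8  pinch little (pronation)
      0.65, 0.75, 0.60, 0.40, # 9  grasp (supination)
      0.45, 0.10, 0.12, 0.70, # 10 radial deviation (supination)
      0.20, 0.55, 0.75, 0.25, # 11 ulnar deviation (supination)
      0.26, 0.76, 0.24, 0.24, # 12 pinch index (supination)
      0.38, 0.61, 0.33, 0.16, # 13 pinch middle (supination)
      0.45, 0.52, 0.40, 0.10, # 14 pinch ring (supination)
      0.35, 0.38, 0.55, 0.06  # 15 pinch little (supination)
    ),
    nrow = 4, ncol = 15,
    dimnames = list(MUSCLES, as.character(CLASS_IDS))
  )
  m
}
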