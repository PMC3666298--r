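#' Pattern reduction: freeze converged gene loci
#'
#' The pattern-reduction operator watches each gene locus across the best
#' fraction of a subpopulation. Once the elite agree on a locus to within a
#' tolerance, the locus is frozen: every individual is set to the consensus
#' value and crossover, mutation and Solis-Wets perturbations subsequently skip
#' it, so the effective dimensionality of the search drops and the worst search
#' directions are filtered out. Freezing is reversible: if the island's best
#' energy stagnates the mask is cleared (see [pr_state()]).
#'
#' `detect_frozen_loci()` freezes a locus iff its value range over the
#' `top_fraction` best individuals is at most the tolerance; torsion loci use
#' the periodic range and the circular mean. The quaternion is frozen only as a
#' whole 4-component block (freezing a subset and renormalizing per individual
#' would reintroduce variance); the consensus quaternion is sign-aligned,
#' averaged and renormalized once.
#'
#' @param pop Evaluated `population`.
#' @param spec A [gene_spec()].
#' @param top_fraction Fraction of best individuals inspected, in `(0, 1]`.
#' @param tolerance Per-locus tolerance vector, or `NULL` for the defaults
#'   (0.25 Angstrom translation, 0.05 quaternion components, 5 degrees torsion).
#' @param generation Generation index recorded on the mask.
#' @return A `frozen_mask`: list with `frozen` (logical per locus), `values`
#'   (consensus value per frozen locus, `NA` elsewhere) and `generation`.
#' @export
detect_frozen_loci <- function(pop, spec, top_fraction = 0.5, tolerance = NULL,
                               generation = NA_integer_) {
  n <- nrow(pop$genes)
  if (n < 2) stop("pattern reduction needs at least 2 individuals", call. = FALSE)
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  g <- spec$n_genes
  if (is.null(tolerance)) tolerance <- default_pr_tolerance(spec)
  tolerance <- rep_len(tolerance, g)

  n_top <- max(2L, ceiling(top_fraction * n))
  n_top <- min(n_top, n)
  top <- order(pop$energy)[seq_len(n_top)]
  G <- pop$genes[top, , drop = FALSE]

  # sign-align quaternions (q and -q encode the same rotation)
  if (length(spec$idx_quat) == 4 && n_top > 1) {
    Q <- G[, spec$idx_quat, drop = FALSE]
    flip <- (Q %*% Q[1, ]) < 0
    Q[flip, ] <- -Q[flip, , drop = FALSE]
    G[, spec$idx_quat] <- Q
  }

  frozen <- logical(g)
  values <- rep(NA_real_, g)
  for (j in seq_len(g)) {
    x <- G[, j]
    if (j %in% spec$idx_tors) {
      rng <- circular_range(x)
      if (rng <= tolerance[j]) {
        frozen[j] <- TRUE
        values[j] <- atan2(mean(sin(x)), mean(cos(x)))
      }
    } else {
      rng <- max(x) - min(x)
      if (rng <= tolerance[j]) {
        frozen[j] <- TRUE
        values[j] <- mean(x)
      }
    }
  }
  # quaternion block: all or nothing, consensus renormalized once
  if (length(spec$idx_quat) == 4) {
    qi <- spec$idx_quat
    if (all(frozen[qi])) {
      values[qi] <- quat_normalize(values[qi])
    } else {
      frozen[qi] <- FALSE
      values[qi] <- NA_real_
    }
  }
  structure(list(frozen = frozen, values = values, generation = generation),
            class = "frozen_mask")
}

default_pr_tolerance <- function(spec, translation = 0.25, quaternion = 0.05,
                                 torsion = 5 * pi / 180) {
  tol <- rep(translation, spec$n_genes)
  tol[spec$idx_quat] <- quaternion
  tol[spec$idx_tors] <- torsion
  tol
}

# periodic range of angles: 2*pi minus the largest gap between sorted values
circular_range <- function(x) {
  if (length(x) < 2) return(0)
  s <- sort(wrap_angle(x))
  gaps <- c(diff(s), 2 * pi - (s[length(s)] - s[1]))
  2 * pi - max(gaps)
}

empty_frozen_mask <- function(spec) {
  structure(list(frozen = logical(spec$n_genes),
                 values = rep(NA_real_, spec$n_genes),
                 generation = NA_integer_),
            class = "frozen_mask")
}

#' Apply a frozen mask to a population
#'
#' Sets every individual's frozen loci to the consensus values. Because the
#' genotypes change, the stored energies are stale; pass `energy_fn` to
#' re-evaluate, otherwise energies are dropped whenever a locus actually
#' changes. An empty mask is the identity.
#'
#' @param pop A `population`.
#' @param mask A `frozen_mask` whose length matches the gene count.
#' @param energy_fn Optional objective to re-evaluate the population.
#' @return A list: `pop`, `units` (re-evaluation count).
#' @export
apply_pattern_reduction <- function(pop, mask, energy_fn = NULL) {
  g <- ncol(pop$genes)
  if (length(mask$frozen) != g) {
    stop(sprintf("frozen mask has %d loci but genomes have %d", length(mask$frozen), g),
         call. = FALSE)
  }
  if (!any(mask$frozen)) return(list(pop = pop, units = c(evaluation = 0L)))
  changed <- FALSE
  for (j in which(mask$frozen)) {
    if (any(pop$genes[, j] != mask$values[j])) changed <- TRUE
    pop$genes[, j] <- mask$values[j]
  }
  evals <- 0L
  if (changed) {
    if (!is.null(energy_fn)) {
      pop$energy <- as.numeric(energy_fn(pop$genes))
      evals <- nrow(pop$genes)
    } else {
      pop$energy <- NULL
    }
  }
  list(pop = pop, units = c(evaluation = evals))
}

#' Per-island pattern-reduction state machine
#'
#' Tracks when to re-detect frozen loci (every `redetect` generations) and when
#' to release the mask on stagnation (best energy not improving for `release`
#' generations). Used inside the island evolution loop; exposed for testing and
#' for audit of the freezing schedule.
#'
#' @param redetect Generations between detections.
#' @param release Stagnant generations after which the mask is cleared.
#' @param top_fraction,tolerance Passed to [detect_frozen_loci()].
#' @return A `pr_state` list.
#' @export
pr_state <- function(redetect = 5L, release = 15L, top_fraction = 0.5,
                     tolerance = NULL) {
  structure(list(redetect = as.integer(redetect), release = as.integer(release),
                 top_fraction = top_fraction, tolerance = tolerance,
                 best_seen = Inf, stagnant = 0L, mask = NULL),
            class = "pr_state")
}

#' @rdname pr_state
#' @param state A `pr_state`.
#' @param pop Evaluated `population`.
#' @param spec A [gene_spec()].
#' @param generation Current island generation (1-based).
#' @return `pr_step()`: a list with the updated `state` and the `mask` to use
#'   this generation (possibly empty).
#' @export
pr_step <- function(state, pop, spec, generation) {
  best <- min(pop$energy)
  if (best < state$best_seen - 1e-12) {
    state$best_seen <- best
    state$stagnant <- 0L
  } else {
    state$stagnant <- state$stagnant + 1L
  }
  if (!is.null(state$mask) && state$stagnant >= state$release) {
    state$mask <- NULL           # un-freeze on stagnation
    state$stagnant <- 0L
  }
  if ((generation - 1L) %% state$redetect == 0L && nrow(pop$genes) >= 2) {
    state$mask <- detect_frozen_loci(pop, spec, state$top_fraction,
                                     state$tolerance, generation)
    if (!any(state$mask$frozen)) state$mask <- NULL
  }
  list(state = state,
       mask = if (is.null(state$mask)) empty_frozen_mask(spec) else state$mask)
}
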