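#' Specification of a synthetic morphometric-style cohort
#'
#' Describes a three-class (or two-class) feature table with the
#' statistical structure the metric learner assumes: a low-dimensional
#' discriminative signal subspace embedded among many nuisance dimensions
#' whose per-feature scales are heterogeneous (mimicking region-wise
#' volumes in mm^3, surface areas in mm^2 and cortical thicknesses in mm),
#' repeated scans per subject with within-subject correlation, and a middle
#' class sitting between the two extreme classes (as mild cognitive
#' impairment sits between healthy controls and Alzheimer's disease).
#'
#' @param n_subjects integer vector of subjects per class (its length sets
#'   the class count). The default `c(23, 38, 29)` keeps the class-size
#'   ratios of a typical dementia cohort (HC:MCI:AD roughly 231:379:286) at
#'   a tenth of the scale.
#' @param scans_range inclusive range of scans per subject, drawn uniformly
#'   (serial imaging typically yields 2-5 scans).
#' @param n_scans_per_class optional exact per-class scan totals; scans are
#'   then spread as evenly as possible over the class's subjects
#'   (overriding `scans_range`), which pins the total N exactly.
#' @param p_signal number of discriminative signal dimensions.
#' @param p_noise number of nuisance dimensions, split across
#'   `feature_block_scales`.
#' @param feature_block_scales named numeric vector of per-block feature
#'   scales for the nuisance dimensions; defaults mimic cortical volumes
#'   (~1e3 mm^3), subcortical volumes (~5e2 mm^3), surface areas
#'   (~7e2 mm^2), mean thickness (~2.5 mm) and thickness s.d. (~0.5 mm).
#' @param effect_size separation (per signal dimension, in units of the
#'   total within-class s.d.) between the two extreme class means.
#' @param intermediate_mix where the middle class sits between the extreme
#'   classes: 0 puts it on class 1, 1 on the last class, 0.5 (default)
#'   half-way. Ignored with two classes.
#' @param between_subject_sd,within_subject_sd s.d. of subject-level means
#'   around the class mean and of scan repeats around the subject mean;
#'   their default ratio (1 : 0.5) makes repeats of one subject markedly
#'   more similar than samples of different subjects, so subject-grouped
#'   validation is meaningful.
#' @param noise_sd s.d. of the nuisance dimensions before block scaling.
#' @param nonlinearity `"none"` (Gaussian classes), `"xor"` (two classes on
#'   the diagonal quadrant pattern, not linearly separable) or `"annulus"`
#'   (one class inside a ring of the other).
#' @param seed integer seed making generation fully deterministic.
#' @return list of class `cka_synth_spec`.
#' @export
synth_spec <- function(n_subjects = c(23L, 38L, 29L),
                       scans_range = c(2L, 5L),
                       n_scans_per_class = NULL,
                       p_signal = 3L, p_noise = 12L,
                       feature_block_scales = c(cortical_volume = 1000,
                                                subcortical_volume = 500,
                                                surface_area = 700,
                                                thickness_avg = 2.5,
                                                thickness_sd = 0.5),
                       effect_size = 1.5, intermediate_mix = 0.5,
                       between_subject_sd = 1, within_subject_sd = 0.5,
                       noise_sd = 1,
                       nonlinearity = c("none", "xor", "annulus"),
                       seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(length(n_subjects) >= 2, all(n_subjects >= 1),
            p_signal >= 1, p_noise >= 0,
            intermediate_mix >= 0, intermediate_mix <= 1,
            effect_size >= 0, between_subject_sd >= 0,
            within_subject_sd >= 0, noise_sd >= 0,
            is.null(n_scans_per_class) ||
              length(n_scans_per_class) == length(n_subjects))
  if (nonlinearity != "none" && length(n_subjects) != 2L)
    stop("the nonlinear families are two-class", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 scans_range = as.integer(scans_range),
                 n_scans_per_class =
                   if (is.null(n_scans_per_class)) NULL
                   else as.integer(n_scans_per_class),
                 p_signal = as.integer(p_signal),
                 p_noise = as.integer(p_noise),
                 feature_block_scales = feature_block_scales,
                 effect_size = effect_size,
                 intermediate_mix = intermediate_mix,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 noise_sd = noise_sd, nonlinearity = nonlinearity,
                 seed = as.integer(seed)),
            class = "cka_synth_spec")
}

# Class means in signal space: extreme classes at -delta/2 and +delta/2 per
# dimension, middle class(es) interpolated by intermediate_mix.
.class_means <- function(spec) {
  C <- length(spec$n_subjects)
  total_sd <- sqrt(spec$between_subject_sd^2 + spec$within_subject_sd^2)
  half <- spec$effect_size * total_sd / 2
  m1 <- rep(-half, spec$p_signal)
  mC <- rep(half, spec$p_signal)
  means <- matrix(NA_real_, C, spec$p_signal)
  means[1, ] <- m1
  means[C, ] <- mC
  if (C > 2) {
    for (c in 2:(C - 1))
      means[c, ] <- (1 - spec$intermediate_mix) * m1 + spec$intermediate_mix * mC
  }
  means
}

#' Generate a synthetic cohort feature table
#'
#' Draws subject-level class means, repeated scans per subject, and
#' block-scaled nuisance dimensions according to a [synth_spec()]. The
#' returned truth metadata records the signal columns and class means, so
#' parameter-recovery tests can compare a fitted projection with the true
#' discriminative subspace.
#'
#' @param spec a [synth_spec()].
#' @return list of class `cka_synth`: `features` (N x P named matrix),
#'   `labels` (factor), `subjects` (character), `truth` (list with
#'   `signal_cols`, `class_means`, `spec`).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "cka_synth_spec"))
  set.seed(spec$seed)
  C <- length(spec$n_subjects)
  class_names <- if (C == 3L) c("HC", "MCI", "AD") else paste0("class", seq_len(C))
  means <- .class_means(spec)
  rows_signal <- list()
  labels <- character(0)
  subjects <- character(0)
  for (c in seq_len(C)) {
    ns <- spec$n_subjects[c]
    scans <- if (!is.null(spec$n_scans_per_class)) {
      tot <- spec$n_scans_per_class[c]
      base <- tot %/% ns
      extra <- tot %% ns
      c(rep(base + 1L, extra), rep(base, ns - extra))
    } else {
      sample(spec$scans_range[1]:spec$scans_range[2], ns, replace = TRUE)
    }
    for (s in seq_len(ns)) {
      subj_mean <- if (spec$nonlinearity == "none") {
        means[c, ] + stats::rnorm(spec$p_signal, sd = spec$between_subject_sd)
      } else if (spec$nonlinearity == "xor") {
        # class 1 on quadrants (+,+)/(-,-), class 2 on (+,-)/(-,+);
        # subjects alternate deterministically between a class's two
        # centers so neither class is linearly separable by imbalance
        signs <- if (c == 1L) {
          if (s %% 2L == 0L) c(1, 1) else c(-1, -1)
        } else {
          if (s %% 2L == 0L) c(1, -1) else c(-1, 1)
        }
        ctr <- c(signs * spec$effect_size,
                 rep(0, max(0, spec$p_signal - 2)))
        ctr + stats::rnorm(spec$p_signal, sd = spec$between_subject_sd / 3)
      } else {  # annulus: class 1 central blob, class 2 on a ring
        if (c == 1L) {
          stats::rnorm(spec$p_signal, sd = spec$between_subject_sd / 2)
        } else {
          u <- stats::rnorm(spec$p_signal)
          r <- 2.5 * spec$effect_size
          r * u / sqrt(sum(u^2)) +
            stats::rnorm(spec$p_signal, sd = spec$between_subject_sd / 3)
        }
      }
      for (r in seq_len(scans[s])) {
        rows_signal[[length(rows_signal) + 1L]] <-
          subj_mean + stats::rnorm(spec$p_signal, sd = spec$within_subject_sd)
        labels <- c(labels, class_names[c])
        subjects <- c(subjects, sprintf("%s_s%02d", class_names[c], s))
      }
    }
  }
  signal <- do.call(rbind, rows_signal)
  N <- nrow(signal)
  colnames(signal) <- paste0("signal_", seq_len(spec$p_signal))
  if (spec$p_noise > 0L) {
    blocks <- spec$feature_block_scales
    sizes <- diff(round(seq(0, spec$p_noise, length.out = length(blocks) + 1)))
    scale_per_col <- rep(blocks, times = sizes)
    # subject-level offsets keep the within-subject correlation in the
    # nuisance dimensions too
    subj_ids <- unique(subjects)
    offs <- matrix(stats::rnorm(length(subj_ids) * spec$p_noise,
                                sd = spec$noise_sd * spec$between_subject_sd),
                   length(subj_ids), spec$p_noise,
                   dimnames = list(subj_ids, NULL))
    noise <- offs[subjects, , drop = FALSE] +
      matrix(stats::rnorm(N * spec$p_noise,
                          sd = spec$noise_sd * spec$within_subject_sd),
             N, spec$p_noise)
    noise <- sweep(noise, 2, scale_per_col, "*")
    colnames(noise) <- paste0(rep(names(blocks), times = sizes), "_",
                              unlist(lapply(sizes, seq_len)))
    features <- cbind(signal, noise)
  } else {
    features <- signal
  }
  rownames(features) <- NULL
  structure(list(features = features,
                 labels = factor(labels, levels = class_names),
                 subjects = subjects,
                 truth = list(signal_cols = seq_len(spec$p_signal),
                              class_means = means, spec = spec)),
            class = "cka_synth")
}

#' @export
print.cka_synth <- function(x, ...) {
  cat(sprintf("synthetic cohort: N = %d samples, P = %d features, %d classes, %d subjects\n",
              nrow(x$features), ncol(x$features), nlevels(x$labels),
              length(unique(x$subjects))))
  invisible(x)
}

#' Canned synthetic instances used across the test suite
#'
#' Deterministic named fixtures:
#' \describe{
#'   \item{`tiny3class`}{N = 30, P = 6: three classes, five subjects each,
#'     two scans per subject; two signal and four nuisance dimensions.}
#'   \item{`xor2class`}{two classes on the XOR quadrant pattern — not
#'     linearly separable, separable after a nonlinear layer.}
#'   \item{`scale-confounded`}{two classes cleanly separated along a single
#'     discriminative feature, plus nine high-variance nuisance features on
#'     volume/area-like scales; the family on which unstandardized
#'     variance-based projections fail and the learned metric must recover
#'     the informative direction.}
#' }
#'
#' @param name fixture tag.
#' @param seed optional seed override (default: the fixture's pinned seed),
#'   used to draw independent replicates of the same family.
#' @return a `cka_synth` (see [synth_generate()]).
#' @export
make_fixture <- function(name = c("tiny3class", "xor2class", "scale-confounded"),
                         seed = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    tiny3class = synth_spec(n_subjects = c(5L, 5L, 5L),
                            n_scans_per_class = c(10L, 10L, 10L),
                            p_signal = 2L, p_noise = 4L,
                            feature_block_scales = c(volume = 800,
                                                     thickness = 2),
                            effect_size = 3, seed = 101L),
    xor2class = synth_spec(n_subjects = c(20L, 20L),
                           n_scans_per_class = c(40L, 40L),
                           p_signal = 2L, p_noise = 2L,
                           feature_block_scales = c(volume = 900,
                                                    thickness = 2),
                           effect_size = 1.5, nonlinearity = "xor",
                           seed = 202L),
    `scale-confounded` = synth_spec(n_subjects = c(15L, 15L),
                                    n_scans_per_class = c(30L, 30L),
                                    p_signal = 1L, p_noise = 9L,
                                    feature_block_scales = c(volume = 1000,
                                                             area = 600,
                                                             thickness = 150),
                                    effect_size = 6, noise_sd = 1,
                                    seed = 303L))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  synth_generate(spec)
}
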