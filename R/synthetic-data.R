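# Baseline residue composition: average bacterial proteome usage.
# Its expected Kyte-Doolittle mean is ~ -0.18, so tilts stay small.
BASE_COMPOSITION <- c(
  A = 0.089, R = 0.055, N = 0.040, D = 0.054, C = 0.012,
  Q = 0.039, E = 0.061, G = 0.074, H = 0.021, I = 0.060,
  L = 0.100, K = 0.064, M = 0.024, F = 0.041, P = 0.044,
  S = 0.058, T = 0.054, W = 0.011, Y = 0.030, V = 0.070
)

# Exponentially tilt a composition so its expected hydropathy hits
# `target`: p_i(beta) ~ p_i * exp(beta * kd_i). The expectation is strictly
# increasing in beta, so uniroot finds the unique solution.
tilt_composition <- function(target, base = BASE_COMPOSITION, scale = kd_scale()) {
  if (abs(target) >= 4.5) {
    abort("infeasible composition target: |target| must be < 4.5")
  }
  kd <- scale[names(base)]
  expected <- function(beta) {
    w <- base * exp(beta * kd)
    sum(w * kd) / sum(w)
  }
  beta <- uniroot(function(b) expected(b) - target, c(-8, 8), tol = 1e-10)$root
  w <- base * exp(beta * kd)
  w / sum(w)
}

# composition cache: tilts are reused across proteins of similar target
tilt_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(target, scale = kd_scale()) {
    key <- sprintf("%s|%.4f", attr(scale, "name") %||% "custom", target)
    if (is.null(cache[[key]])) cache[[key]] <- tilt_composition(target, scale = scale)
    cache[[key]]
  }
})

draw_residues <- function(n, comp) {
  if (n <= 0L) return("")
  paste0(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

#' Specification of a synthetic proteome
#'
#' Defaults emulate a lactic-acid-bacterium draft proteome: ~3,000 proteins
#' of which ~6% carry a planted surface-localization feature (secreted far
#' outnumbering lipoproteins and LPXTG anchors), a background GRAVY
#' distribution centred near -0.18, and surface mature regions shifted
#' toward more negative GRAVY by `surface_gravy_shift`. The N-terminal scan
#' region of background proteins is drawn from a hydrophilic-tilted
#' composition (`nterm_hydropathy`), emulating the charged, soluble
#' N-termini of cytosolic proteins; the remainder of each chain is tilted
#' so the whole-protein expectation still hits `background_gravy_target`.
#'
#' @param n_proteins Number of proteins (default 3000, >= 10).
#' @param frac_secreted,frac_lipoprotein,frac_lpxtg Planted category
#'   fractions (defaults 0.060, 0.0005, 0.001); converted to counts with
#'   `round()` unless explicit counts are given.
#' @param n_secreted,n_lipoprotein,n_lpxtg Optional explicit planted
#'   counts overriding the fractions.
#' @param length_mean,length_sd,length_min Protein length distribution
#'   (normal, rounded, truncated at `length_min`; defaults 300/120/60).
#' @param background_gravy_target Expected GRAVY of background residues
#'   (default -0.18).
#' @param surface_gravy_shift Added to the background target for the
#'   mature regions of planted surface proteins (default -0.03).
#' @param nterm_hydropathy Expected hydropathy of the background
#'   N-terminal scan region (default -0.8).
#' @param seed Integer seed; every draw is a pure function of spec + seed.
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(n_proteins = 3000L,
                          frac_secreted = 0.060, frac_lipoprotein = 0.0005,
                          frac_lpxtg = 0.001,
                          n_secreted = NULL, n_lipoprotein = NULL, n_lpxtg = NULL,
                          length_mean = 300, length_sd = 120, length_min = 60L,
                          background_gravy_target = -0.18,
                          surface_gravy_shift = -0.03,
                          nterm_hydropathy = -0.8,
                          seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 10L) abort("`n_proteins` must be >= 10")
  fr <- c(frac_secreted, frac_lipoprotein, frac_lpxtg)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1) {
    abort("category fractions must lie in [0,1] and sum to < 1")
  }
  if (length_min < 60L) abort("`length_min` must be >= 60")
  spec <- list(
    n_proteins = n_proteins,
    n_secreted = as.integer(n_secreted %||% round(frac_secreted * n_proteins)),
    n_lipoprotein = as.integer(n_lipoprotein %||% round(frac_lipoprotein * n_proteins)),
    n_lpxtg = as.integer(n_lpxtg %||% round(frac_lpxtg * n_proteins)),
    length_mean = length_mean, length_sd = length_sd,
    length_min = as.integer(length_min),
    background_gravy_target = background_gravy_target,
    surface_gravy_shift = surface_gravy_shift,
    nterm_hydropathy = nterm_hydropathy,
    seed = as.integer(seed)
  )
  if (spec$n_secreted + spec$n_lipoprotein + spec$n_lpxtg >= n_proteins) {
    abort("planted counts exceed the proteome size")
  }
  structure(spec, class = "proteome_spec")
}

HSTRETCH_AA <- c("L", "I", "V", "F")  # strongly hydrophobic, A/C-free

# background sequence: hydrophilic N-terminal scan region, body tilted so
# the whole-chain expectation hits the overall target
draw_background_seq <- function(len, target, nterm_target, scale) {
  n_nt <- min(52L, len %/% 2L)
  body_target <- (len * target - n_nt * nterm_target) / (len - n_nt)
  paste0(
    draw_residues(n_nt, tilt_cached(nterm_target, scale)),
    draw_residues(len - n_nt, tilt_cached(body_target, scale))
  )
}

# spacer compositions exclude letters that could spawn a competing motif
spacer_comp <- function(comp, drop) {
  comp <- comp[setdiff(names(comp), drop)]
  comp / sum(comp)
}

build_secreted <- function(len, params, mature_comp, spacer) {
  h <- params$h_window
  prefix <- paste0("MK", draw_residues2(h, HSTRETCH_AA))
  min_c <- max(params$sp_cleave_min, nchar(prefix) + 3L)
  cle <- sample_one(seq.int(min_c, params$sp_cleave_max))
  n_spacer <- cle - 2L - nchar(prefix) - 1L   # up to the A-X-A start
  axa <- paste0("A", draw_residues2(1L, setdiff(names(spacer), "A")), "A")
  mature_len <- max(len - cle, 10L)
  seq <- paste0(
    prefix, draw_residues(n_spacer, spacer), axa,
    draw_residues(mature_len, mature_comp)
  )
  list(sequence = seq, cleavage_pos = cle)
}

build_lipoprotein <- function(len, params, mature_comp, spacer) {
  h <- params$h_window
  prefix <- paste0("MK", draw_residues2(h, HSTRETCH_AA))
  min_cys <- max(params$lipobox_c_min, nchar(prefix) + 4L)
  cys <- sample_one(seq.int(min_cys, params$lipobox_c_max))
  n_spacer <- cys - 4L - nchar(prefix)
  lipobox <- paste0("L", sample(c("A", "S"), 1L), sample(c("A", "G"), 1L), "C")
  rest <- max(len - cys, 10L)
  seq <- paste0(
    prefix, draw_residues(n_spacer, spacer), lipobox,
    draw_residues(rest, mature_comp)
  )
  list(sequence = seq, lipobox_pos = cys - 3L)
}

build_lpxtg <- function(len, params, body_comp) {
  tm <- draw_residues2(params$tm_window, HSTRETCH_AA)
  tail_pool <- c("S", "T", "N", "Q", "G", "E")
  tail <- strsplit(draw_residues2(params$tail_len, tail_pool), "")[[1]]
  kr_at <- sample(params$tail_len, max(params$tail_min_kr, 3L))
  tail[kr_at] <- sample(c("K", "R"), length(kr_at), replace = TRUE)
  motif <- paste0("LP", draw_residues2(1L, setdiff(CANONICAL_AA, c("P"))), "TG")
  suffix <- paste0(motif, tm, paste0(tail, collapse = ""))
  body_len <- max(len - nchar(suffix), 20L)
  seq <- paste0(draw_residues(body_len, body_comp), suffix)
  list(sequence = seq, lpxtg_pos = body_len + 1L)
}

draw_residues2 <- function(n, pool) {
  paste0(pool[sample.int(length(pool), n, replace = TRUE)], collapse = "")
}

sample_one <- function(v) v[sample.int(length(v), 1L)]

#' Generate a labeled synthetic proteome
#'
#' Draws a proteome to a [proteome_spec()]: background proteins from the
#' tilted composition, plus planted secreted / lipoprotein / LPXTG-anchored
#' proteins whose constructs meet the classifier's documented definitions
#' at the supplied parameters. Every planted protein is validated against
#' [classify_protein()] at generation time (and redrawn from the seeded
#' stream if a random segment accidentally spawns a higher-precedence
#' motif), so detector recall on the planted truth is 1 by construction;
#' generation fails loudly if validation cannot be satisfied.
#'
#' @param spec A [proteome_spec()].
#' @param params Classifier parameters the planted motifs must satisfy.
#' @param scale Hydropathy scale.
#' @return A list of class `labeled_proteome`: `proteome` (tibble `id`,
#'   `description`, `sequence`) and `truth` (tibble `protein_id`,
#'   `category`, `cleavage_pos`, `lipobox_pos`, `lpxtg_pos`).
#' @export
generate_proteome <- function(spec = proteome_spec(),
                              params = classifier_params(),
                              scale = kd_scale()) {
  stopifnot(inherits(spec, "proteome_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_proteins
    lens <- pmax(round(rnorm(n, spec$length_mean, spec$length_sd)), spec$length_min)
    cats <- sample(rep(
      c("secreted", "lipoprotein", "lpxtg_anchored", "none"),
      c(spec$n_secreted, spec$n_lipoprotein, spec$n_lpxtg,
        n - spec$n_secreted - spec$n_lipoprotein - spec$n_lpxtg)
    ))
    mature_comp <- tilt_cached(
      spec$background_gravy_target + spec$surface_gravy_shift, scale
    )
    bg_comp <- tilt_cached(spec$background_gravy_target, scale)
    sp_secr <- spacer_comp(bg_comp, c("A", "C"))
    sp_lipo <- spacer_comp(bg_comp, "C")

    ids <- sprintf("prot_%05d", seq_len(n))
    seqs <- character(n)
    cleave <- rep(NA_integer_, n)
    lipo <- rep(NA_integer_, n)
    lpx <- rep(NA_integer_, n)

    for (i in seq_len(n)) {
      if (cats[i] == "none") {
        seqs[i] <- draw_background_seq(
          lens[i], spec$background_gravy_target, spec$nterm_hydropathy, scale
        )
        next
      }
      ok <- FALSE
      for (try in 1:50) {
        cand <- switch(cats[i],
          secreted = build_secreted(lens[i], params, mature_comp, sp_secr),
          lipoprotein = build_lipoprotein(lens[i], params, mature_comp, sp_lipo),
          lpxtg_anchored = build_lpxtg(lens[i], params, mature_comp)
        )
        call <- classify_protein(ids[i], cand$sequence, params, scale)
        planted_ok <- call$category == cats[i] && switch(cats[i],
          secreted = identical(call$cleavage_pos, as.integer(cand$cleavage_pos)),
          lipoprotein = identical(call$lipobox_pos, as.integer(cand$lipobox_pos)),
          lpxtg_anchored = identical(call$lpxtg_pos, as.integer(cand$lpxtg_pos))
        )
        if (planted_ok) {
          seqs[i] <- cand$sequence
          cleave[i] <- as.integer(cand$cleavage_pos %||% NA_integer_)
          lipo[i] <- as.integer(cand$lipobox_pos %||% NA_integer_)
          lpx[i] <- as.integer(cand$lpxtg_pos %||% NA_integer_)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(paste0(
          "planted ", cats[i], " construct failed validation for ", ids[i],
          ": classifier params incompatible with the generator's constructs"
        ))
      }
    }

    proteome <- tibble::tibble(id = ids, description = "", sequence = seqs)
    attr(proteome, "source_label") <- sprintf("synthetic proteome (seed %d)", spec$seed)
    structure(
      list(
        proteome = proteome,
        truth = tibble::tibble(
          protein_id = ids, category = cats,
          cleavage_pos = cleave, lipobox_pos = lipo, lpxtg_pos = lpx
        ),
        spec = spec
      ),
      class = "labeled_proteome"
    )
  })
}

#' @export
print.labeled_proteome <- function(x, ...) {
  tab <- table(x$truth$category)
  cat(sprintf(
    "<labeled_proteome> %d proteins (seed %d): %s\n",
    nrow(x$proteome), x$spec$seed,
    paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

BIOFILM_FOLD <- c(Negative = 1.0, Weak = 1.5, Moderate = 3.0, Strong = 5.0)

#' Generate a biofilm plate with a known class
#'
#' Replicate ODs are drawn around class-consistent means (test mean =
#' `BIOFILM_FOLD[true_class] * odc_mean`, e.g. 3x the control for
#' Moderate). The noise level is checked for feasibility: the distance of
#' each group mean to the relevant class boundaries must exceed three
#' standard errors so the class survives the noise with probability
#' > 0.99. Since "Negative" sits exactly on the inclusive ODt <= ODc
#' boundary, it is only generable with `noise_sd = 0`.
#'
#' @param true_class One of Negative / Weak / Moderate / Strong.
#' @param odc_mean Control mean OD (> 0).
#' @param noise_sd Gaussian noise SD on each replicate.
#' @param n_replicates Replicates per group.
#' @param seed Integer seed.
#' @return Plate tibble (`well`, `group`, `od`) with attribute
#'   `true_class`, ready for [assay_report()] or [biofilm_classify()].
#' @export
generate_plate <- function(true_class, odc_mean, noise_sd = 0.001,
                           n_replicates = 4L, seed = 1L) {
  true_class <- match.arg(true_class, names(BIOFILM_FOLD))
  if (odc_mean <= 0) abort("`odc_mean` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  fold <- BIOFILM_FOLD[[true_class]]
  odt_mean <- fold * odc_mean
  # class boundaries (in folds of ODc) flanking the target mean
  bounds <- switch(true_class,
    Negative = 1, Weak = c(1, 2), Moderate = c(2, 4), Strong = 4
  )
  se <- function(k) noise_sd * sqrt((1 + k^2) / n_replicates)
  margin <- abs(odt_mean - bounds * odc_mean)
  if (any(margin < 3 * se(bounds))) {
    abort(paste0(
      "infeasible noise: class '", true_class,
      "' is not preserved with probability > 0.99 at noise_sd = ", noise_sd
    ))
  }
  withr::with_seed(seed, {
    od_t <- rnorm(n_replicates, odt_mean, noise_sd)
    od_c <- rnorm(n_replicates, odc_mean, noise_sd)
  })
  plate <- tibble::tibble(
    well = sprintf("%s%d", rep(c("T", "C"), each = n_replicates), rep(seq_len(n_replicates), 2)),
    group = rep(c("test", "control"), each = n_replicates),
    od = pmax(c(od_t, od_c), 0)
  )
  attr(plate, "true_class") <- true_class
  plate
}

#' Generate a stress-tolerance panel for a set of isolates
#'
#' Seeded log-CFU endpoints for the acid, bile, and lysozyme exposures plus
#' mean antagonism halo diameters, in the long format consumed by
#' [build_feature_matrix()]. When `dominant` names an isolate, that isolate
#' is constructed to hold the best value in all four variables (largest
#' retention in every stressor and the widest halo) with a fixed margin
#' over the runner-up — the profile of a clearly superior probiotic
#' candidate. With `noise_sd = 0` and no dominant isolate all isolates are
#' identical, which downstream standardization correctly rejects.
#'
#' @param n_isolates Number of isolates (>= 2).
#' @param isolate_ids Optional ids (default M1, M2, ...).
#' @param dominant Id of the dominant isolate, or `NULL`.
#' @param base_log_retention Mean log10 retention (Delta log CFU) of
#'   non-dominant isolates (default -0.5, i.e. ~32% survival).
#' @param base_halo_mm Mean halo of non-dominant isolates (default 13).
#' @param noise_sd SD of the Gaussian noise on Delta log values
#'   (`10 * noise_sd` on halos).
#' @param seed Integer seed.
#' @return Long tibble: `isolate_id`, `stressor`, `log_cfu_initial`,
#'   `log_cfu_final`, `antagonism_mm`.
#' @export
generate_stress_panel <- function(n_isolates = 3L, isolate_ids = NULL,
                                  dominant = NULL,
                                  base_log_retention = -0.5,
                                  base_halo_mm = 13,
                                  noise_sd = 0.05, seed = 1L) {
  n_isolates <- as.integer(n_isolates)
  if (n_isolates < 2L) abort("`n_isolates` must be >= 2")
  ids <- isolate_ids %||% paste0("M", seq_len(n_isolates))
  stopifnot(length(ids) == n_isolates)
  if (!is.null(dominant) && !dominant %in% ids) {
    abort(paste0("dominant isolate '", dominant, "' is not among the isolate ids"))
  }
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(isolate_id = ids, stressor = STRESSORS)
    grid$log_cfu_initial <- round(runif(nrow(grid), 8.2, 8.8), 3)
    dlog <- pmin(base_log_retention + rnorm(nrow(grid), 0, noise_sd), 0)
    halo <- setNames(base_halo_mm + rnorm(n_isolates, 0, 10 * noise_sd), ids)
    if (!is.null(dominant)) {
      for (st in STRESSORS) {
        rows <- grid$stressor == st
        best_other <- max(dlog[rows & grid$isolate_id != dominant])
        # strictly the best retention, capped below zero
        dom <- min(best_other + 0.3, 0)
        if (dom <= best_other) dom <- best_other / 2
        dlog[rows & grid$isolate_id == dominant] <- dom
      }
      halo[dominant] <- max(halo[setdiff(ids, dominant)]) + 4
    }
    grid$log_cfu_final <- round(grid$log_cfu_initial + dlog, 3)
    grid$antagonism_mm <- round(unname(halo[grid$isolate_id]), 2)
  })
  grid
}
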