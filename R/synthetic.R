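#' Specification of a synthetic decoy benchmark
#'
#' The generator emulates the three inputs the pipeline consumes: native-like
#' chains (self-avoiding random walks at C-alpha spacing), coordinate-
#' perturbed decoys spanning low to high quality, sequence-predictor-like
#' noisy distance maps, and distance-based quality labels in \[0,1\].
#'
#' @param n_targets number of protein targets.
#' @param length_range integer `c(L_min, L_max)`, lengths sampled uniformly;
#'   `L_min >= 5`.
#' @param decoys_per_target decoys per target (>= 2), assigned round-robin
#'   across `decoy_noise_sigmas` so every pool spans the quality range.
#' @param decoy_noise_sigmas per-atom Gaussian perturbation scales in
#'   Angstrom.
#' @param predictor_noise_sigma Gaussian noise added (symmetrically) to the
#'   native distance map to mimic an imperfect sequence-based predictor
#'   (Angstrom).
#' @param bond_length consecutive C-alpha spacing in Angstrom (default 3.8).
#' @param threshold contact cutoff in Angstrom used for the quality label and
#'   downstream filtering (default 16).
#' @param gly_fraction fraction of glycine residues (which have no C-beta,
#'   exercising the representative-atom fallback).
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return validated list of class `dmqa_synthetic_spec`.
#' @export
synthetic_spec <- function(n_targets = 30L, length_range = c(30L, 60L),
                           decoys_per_target = 20L,
                           decoy_noise_sigmas = c(0.25, 0.5, 1, 2, 4),
                           predictor_noise_sigma = 0.5,
                           bond_length = 3.8, threshold = 16,
                           gly_fraction = 0.1, seed = 1L) {
  spec <- list(n_targets = as.integer(n_targets),
               length_range = as.integer(length_range),
               decoys_per_target = as.integer(decoys_per_target),
               decoy_noise_sigmas = as.numeric(decoy_noise_sigmas),
               predictor_noise_sigma = predictor_noise_sigma,
               bond_length = bond_length, threshold = threshold,
               gly_fraction = gly_fraction, seed = as.integer(seed))
  if (spec$n_targets < 1) stop("n_targets must be >= 1")
  if (length(spec$length_range) != 2 || spec$length_range[1] < 5 ||
      spec$length_range[2] < spec$length_range[1])
    stop("length_range must be c(L_min, L_max) with L_min >= 5")
  if (spec$decoys_per_target < 2) stop("decoys_per_target must be >= 2")
  if (any(spec$decoy_noise_sigmas < 0) || spec$predictor_noise_sigma < 0)
    stop("noise sigmas must be >= 0")
  if (spec$bond_length <= 0 || spec$threshold <= 0)
    stop("bond_length and threshold must be positive")
  if (spec$gly_fraction < 0 || spec$gly_fraction > 1)
    stop("gly_fraction must lie in [0,1]")
  class(spec) <- "dmqa_synthetic_spec"
  spec
}

#' Generate a self-avoiding chain
#'
#' A random walk with fixed step length `bond_length` in which no
#' non-consecutive pair of residues comes closer than `min_separation`
#' (4 Angstrom by default, a typical excluded-volume radius for C-alpha
#' traces). Dead ends are resolved by backtracking, with bounded restarts.
#'
#' @param length number of residues (>= 5).
#' @param bond_length step length in Angstrom.
#' @param min_separation minimum non-consecutive inter-residue distance.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param max_restarts restarts before giving up.
#' @return `length` x 3 coordinate matrix.
#' @export
generate_chain <- function(length, bond_length = 3.8, min_separation = 4,
                           seed = NULL, max_restarts = 50L) {
  stopifnot(is_count(length, min = 5))
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      coords <- matrix(NA_real_, length, 3)
      coords[1, ] <- c(0, 0, 0)
      i <- 2L
      fails <- 0L
      while (i <= length) {
        placed <- FALSE
        for (try in 1:60) {
          v <- stats::rnorm(3)
          v <- v / sqrt(sum(v^2)) * bond_length
          cand <- coords[i - 1L, ] + v
          if (i > 2L) {
            prev <- coords[seq_len(i - 2L), , drop = FALSE]
            d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
              (prev[, 3] - cand[3])^2
            if (min(d2) < min_separation^2) next
          }
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
        if (placed) {
          i <- i + 1L
        } else {
          # dead end: back up a few residues and retry
          fails <- fails + 1L
          if (fails > 20L) break
          i <- max(2L, i - 3L)
        }
      }
      if (i > length) return(coords)
    }
    stop(sprintf(
      "chain placement failed after %d restarts; try a smaller length than %d",
      max_restarts, length))
  })
}

# idealized C-beta pseudo-atom 1.53 A off the C-alpha trace, pointing away
# from the local chain direction; deterministic in the C-alpha coordinates
derive_cb <- function(ca) {
  L <- nrow(ca)
  cb <- ca
  for (i in seq_len(L)) {
    if (i == 1) {
      d <- ca[1, ] - ca[2, ]
    } else if (i == L) {
      d <- ca[L, ] - ca[L - 1, ]
    } else {
      u <- ca[i, ] - ca[i - 1, ]
      v <- ca[i, ] - ca[i + 1, ]
      d <- u / sqrt(sum(u^2)) + v / sqrt(sum(v^2))
      if (sum(d^2) < 1e-12) d <- c(u[2] * v[3] - u[3] * v[2],
                                   u[3] * v[1] - u[1] * v[3],
                                   u[1] * v[2] - u[2] * v[1])
    }
    cb[i, ] <- ca[i, ] + 1.53 * d / sqrt(sum(d^2))
  }
  cb
}

#' Distance-agreement quality score
#'
#' A GDT-TS-like superposition-free label: the mean, over the cutoffs
#' `c(1, 2, 4, 8)` Angstrom, of the fraction of residue pairs `i < j` with
#' native distance `<= threshold` whose decoy-vs-native distance error is
#' below the cutoff. 1 for a perfect model, approaching 0 for random ones.
#'
#' @param native_map,decoy_map L x L distance matrices over the same residue
#'   set.
#' @param threshold contact cutoff in Angstrom (default 16).
#' @param cutoffs error cutoffs in Angstrom.
#' @return quality score in \[0,1\].
#' @export
distance_quality_score <- function(native_map, decoy_map, threshold = 16,
                                   cutoffs = c(1, 2, 4, 8)) {
  stopifnot(all(dim(native_map) == dim(decoy_map)))
  sel <- upper.tri(native_map) & native_map <= threshold
  if (!any(sel)) return(NA_real_)
  err <- abs(decoy_map[sel] - native_map[sel])
  mean(vapply(cutoffs, function(ct) mean(err < ct), numeric(1)))
}

#' Perturb a structure into a decoy and score it
#'
#' Adds isotropic Gaussian noise of scale `sigma` independently to every
#' atom, and computes the [distance_quality_score()] between the native and
#' perturbed distance maps. A zero-noise decoy equals the native and has
#' quality exactly 1.
#'
#' @param native n x 3 coordinate matrix (representative atoms).
#' @param sigma per-atom noise scale in Angstrom (>= 0).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param threshold contact cutoff for the quality label.
#' @return `list(coords = perturbed matrix, true_quality = score)`.
#' @export
make_decoy <- function(native, sigma, seed = NULL, threshold = 16) {
  stopifnot(is.matrix(native), ncol(native) == 3, sigma >= 0)
  with_seed(seed, {
    coords <- native + matrix(stats::rnorm(base::length(native), sd = sigma),
                              nrow(native), 3)
    if (sigma == 0) coords <- native
    q <- distance_quality_score(as.matrix(stats::dist(native)),
                                as.matrix(stats::dist(coords)),
                                threshold = threshold)
    list(coords = coords, true_quality = q)
  })
}

write_decoy_pdb <- function(file, ca, cb, is_gly) {
  L <- nrow(ca)
  xyz <- c()
  resno <- c()
  resid <- c()
  elety <- c()
  for (i in seq_len(L)) {
    xyz <- c(xyz, ca[i, ])
    resno <- c(resno, i)
    resid <- c(resid, if (is_gly[i]) "GLY" else "ALA")
    elety <- c(elety, "CA")
    if (!is_gly[i]) {
      xyz <- c(xyz, cb[i, ])
      resno <- c(resno, i)
      resid <- c(resid, "ALA")
      elety <- c(elety, "CB")
    }
  }
  bio3d::write.pdb(file = file, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep("A", length(resno)))
  invisible(file)
}

write_map_txt <- function(file, m) {
  utils::write.table(format(m, digits = 8, trim = TRUE, scientific = FALSE),
                     file, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Generate a synthetic decoy benchmark on disk
#'
#' For each target: a self-avoiding native chain; a predicted distance map
#' equal to the native representative-atom map plus symmetric Gaussian
#' predictor noise (clipped at 0); and a pool of decoys perturbed at the
#' configured noise scales, with distance-agreement quality labels. Emits
#' exactly the external formats the real pipeline consumes: single-chain PDB
#' files (C-alpha plus idealized C-beta pseudo-atoms; glycines exercise the
#' C-alpha fallback), plain-text L x L distance matrices, a labels TSV
#' (`target_id`, `model_id`, `true_quality`) and a dataset manifest TSV.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory, created if needed; `NULL` generates
#'   in memory only. Manifest paths are relative to this directory.
#' @return invisibly, `list(targets = list of per-target data, manifest =
#'   data.frame, labels = data.frame)`. Each target holds `target_id`,
#'   `length`, `native_ca`, `native_rep`, `predicted_map`, `is_gly` and a
#'   `decoys` data.frame.
#' @export
generate_dataset <- function(spec = synthetic_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "dmqa_synthetic_spec"))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "pdb"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "maps"), recursive = TRUE,
               showWarnings = FALSE)
  }
  targets <- vector("list", spec$n_targets)
  manifest <- list()
  labels <- list()
  with_seed(spec$seed, {
    lengths <- sample(seq(spec$length_range[1], spec$length_range[2]),
                      spec$n_targets, replace = TRUE)
    sigmas <- rep(spec$decoy_noise_sigmas,
                  length.out = spec$decoys_per_target)
    for (t in seq_len(spec$n_targets)) {
      tid <- sprintf("T%03d", t)
      L <- lengths[t]
      ca <- generate_chain(L, spec$bond_length, seed = NULL)
      is_gly <- stats::runif(L) < spec$gly_fraction
      cb <- derive_cb(ca)
      rep_xyz <- ca
      rep_xyz[!is_gly, ] <- cb[!is_gly, ]
      native_map <- as.matrix(stats::dist(rep_xyz))
      noise <- matrix(stats::rnorm(L * L, sd = spec$predictor_noise_sigma),
                      L, L)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      pred <- pmax(native_map + noise, 0)
      diag(pred) <- 0
      # manifest paths are relative to out_dir so reruns into different
      # directories are byte-identical
      map_path <- file.path("maps", paste0(tid, ".map"))
      if (!is.null(out_dir)) write_map_txt(file.path(out_dir, map_path), pred)
      decoys <- data.frame(model_id = sprintf("%s_D%03d", tid,
                                              seq_len(spec$decoys_per_target)),
                           sigma = sigmas, true_quality = NA_real_,
                           pdb_path = NA_character_,
                           stringsAsFactors = FALSE)
      decoy_coords <- vector("list", spec$decoys_per_target)
      for (d in seq_len(spec$decoys_per_target)) {
        dec <- make_decoy(rep_xyz, sigmas[d], seed = NULL,
                          threshold = spec$threshold)
        decoys$true_quality[d] <- dec$true_quality
        decoy_coords[[d]] <- dec$coords
        # rebuild the full atom set: representative atoms are the decoy
        # coordinates; the CA of non-glycine residues gets its own noise
        dec_ca <- ca + matrix(stats::rnorm(L * 3, sd = sigmas[d]), L, 3)
        dec_ca[is_gly, ] <- dec$coords[is_gly, ]
        decoys$pdb_path[d] <- file.path("pdb",
                                        paste0(decoys$model_id[d], ".pdb"))
        if (!is.null(out_dir))
          write_decoy_pdb(file.path(out_dir, decoys$pdb_path[d]),
                          dec_ca, dec$coords, is_gly)
      }
      targets[[t]] <- list(target_id = tid, length = L, native_ca = ca,
                           native_rep = rep_xyz, is_gly = is_gly,
                           predicted_map = pred,
                           map_path = map_path, decoys = decoys,
                           decoy_coords = decoy_coords)
      manifest[[t]] <- data.frame(target_id = tid,
                                  model_id = decoys$model_id,
                                  length = L,
                                  pdb_path = decoys$pdb_path,
                                  map_path = map_path,
                                  true_quality = decoys$true_quality,
                                  stringsAsFactors = FALSE)
      labels[[t]] <- data.frame(target_id = tid,
                                model_id = decoys$model_id,
                                true_quality = decoys$true_quality,
                                stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, manifest)
  labels <- do.call(rbind, labels)
  if (!is.null(out_dir)) {
    write.table(format_num_df(manifest), file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(format_num_df(labels), file.path(out_dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(targets = targets, manifest = manifest, labels = labels))
}

# stable numeric formatting so reruns are byte-identical
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(v)
        if (is.na(v)) "" else format(v, digits = 10, trim = TRUE,
                                     scientific = FALSE), character(1))
  }
  df
}
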