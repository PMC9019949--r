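#' Construct a distance map object
#'
#' An L x L symmetric, non-negative matrix of inter-residue distances in
#' Angstrom. Entries of a model-derived map may be `Inf` for residues missing
#' from the model (they are removed by the mutual threshold filter before any
#' arithmetic).
#'
#' @param values numeric L x L matrix of distances (Angstrom).
#' @param source `"predicted"` (from sequence) or `"model"` (from
#'   coordinates).
#' @return an object of class `dmqa_distance_map` with elements `values`,
#'   `length` and `source`.
#' @export
distance_map <- function(values, source = c("predicted", "model")) {
  source <- match.arg(source)
  if (!is.matrix(values) || !is.numeric(values))
    stop("distance map values must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop(sprintf("distance map must be square, got %d x %d",
                 nrow(values), ncol(values)))
  if (anyNA(values)) stop("distance map contains NA values")
  if (any(values < 0)) stop("distance map contains negative distances")
  if (any(diag(values) != 0)) stop("distance map diagonal must be exactly 0")
  fin <- is.finite(values)
  if (!isTRUE(all.equal(values[fin], t(values)[fin], tolerance = 0)) ||
      !identical(fin, t(fin)))
    stop("distance map must be symmetric")
  structure(list(values = values, length = nrow(values), source = source),
            class = "dmqa_distance_map")
}

#' @export
print.dmqa_distance_map <- function(x, ...) {
  cat(sprintf("<distance map> L = %d, source = %s\n", x$length, x$source))
  invisible(x)
}

as_dist_matrix <- function(x, what = "distance map") {
  if (inherits(x, "dmqa_distance_map")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("%s must be a dmqa_distance_map or numeric matrix", what))
}

# quick structural sanity scan of coordinate records so a malformed file is
# reported with its line number (the full parse is delegated to bio3d)
scan_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0)
    stop(sprintf("PDB format error in '%s': no ATOM records found", path))
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("PDB format error in '%s' at line %d: truncated ATOM record",
                   path, i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf(
        "PDB format error in '%s' at line %d: non-numeric coordinate field",
        path, i))
  }
  invisible(TRUE)
}

#' Distance map from the coordinates of a structural model
#'
#' Computes the L x L Euclidean distance matrix between representative atoms
#' of the residues of a protein model. The representative atom is C-beta,
#' falling back to C-alpha for glycine or when C-beta is absent (the
#' convention of sequence-based distance predictors); `atom = "ca"` forces
#' C-alpha throughout. Only the first model and first chain are used; for
#' alternate locations the highest-occupancy one is kept and insertion codes
#' are processed in file order.
#'
#' @param pdb path to a PDB file, a `bio3d` pdb object, or an L x 3 numeric
#'   coordinate matrix (one representative atom per residue).
#' @param length expected sequence length L. When supplied, residues are
#'   indexed by their PDB residue number within 1..L; rows/columns of
#'   residues missing from the model are set to `Inf` (above any threshold,
#'   so the mutual filter removes them) with a warning. When `NULL`, the
#'   residues present define L in order of appearance.
#' @param atom representative-atom convention, `"cb"` (default,
#'   C-beta with C-alpha fallback) or `"ca"`.
#' @return a [distance_map()] with `source = "model"`; attribute `atom`
#'   records the convention, attribute `missing` the indices of absent
#'   residues.
#' @export
model_distance_map <- function(pdb, length = NULL, atom = c("cb", "ca")) {
  atom <- match.arg(atom)
  coords <- NULL
  if (is.matrix(pdb) && is.numeric(pdb)) {
    if (ncol(pdb) != 3) stop("coordinate matrix must have 3 columns")
    coords <- pdb
    resno <- seq_len(nrow(pdb))
  } else {
    if (is.character(pdb)) {
      if (!file.exists(pdb)) stop(sprintf("PDB file not found: '%s'", pdb))
      scan_pdb_coords(pdb)
      pdb <- tryCatch(bio3d::read.pdb(pdb, verbose = FALSE),
                      error = function(e)
                        stop(sprintf("PDB format error in '%s': %s",
                                     pdb, conditionMessage(e))))
    }
    if (!inherits(pdb, "pdb")) stop("pdb must be a path, pdb object or matrix")
    at <- pdb$atom
    at <- at[at$type %in% c("ATOM", "HETATM") & !is.na(at$resno), , drop = FALSE]
    chain1 <- at$chain[1]
    if (!is.na(chain1)) at <- at[is.na(at$chain) | at$chain == chain1, , drop = FALSE]
    # residue identity: (resno, insert) in file order
    ins <- ifelse(is.na(at$insert), "", at$insert)
    rid <- paste(at$resno, ins, sep = "_")
    resids <- unique(rid)
    pick <- function(sub, elety) {
      cand <- sub[sub$elety == elety, , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      occ <- cand$o
      occ[is.na(occ)] <- 1
      cand[which.max(occ), , drop = FALSE]
    }
    rows <- vector("list", length(resids))
    resno <- integer(length(resids))
    for (i in seq_along(resids)) {
      sub <- at[rid == resids[i], , drop = FALSE]
      rep_at <- NULL
      if (atom == "cb" && !identical(toupper(sub$resid[1]), "GLY"))
        rep_at <- pick(sub, "CB")
      if (is.null(rep_at)) rep_at <- pick(sub, "CA")
      if (is.null(rep_at))
        stop(sprintf("residue %d (%s %s) has no usable %s/CA atom",
                     i, sub$resid[1], resids[i],
                     if (atom == "cb") "CB" else "CA"))
      rows[[i]] <- c(rep_at$x, rep_at$y, rep_at$z)
      resno[i] <- sub$resno[1]
    }
    coords <- do.call(rbind, rows)
  }
  if (nrow(coords) < 2)
    stop("degenerate input: a model needs at least 2 resolvable residues")
  if (anyNA(coords)) stop("model contains NA coordinates")

  missing <- integer(0)
  if (is.null(length)) {
    L <- nrow(coords)
    idx <- seq_len(L)
  } else {
    stopifnot(is_count(length, min = 2))
    L <- as.integer(length)
    if (anyDuplicated(resno))
      stop("duplicate residue numbers; cannot index by position with `length`")
    if (any(resno < 1 | resno > L))
      stop(sprintf(
        "model residue numbers outside 1..%d (model has %d residues): %s",
        L, nrow(coords),
        paste(head(resno[resno < 1 | resno > L], 5), collapse = ", ")))
    idx <- resno
    missing <- setdiff(seq_len(L), resno)
    if (length(missing) > 0)
      warning(sprintf(
        "%d residue(s) missing from model (indices %s); their distances are set above any threshold",
        base::length(missing),
        paste(head(missing, 10), collapse = ", ")))
  }
  d <- matrix(Inf, L, L)
  d[idx, idx] <- as.matrix(stats::dist(coords))
  diag(d) <- 0
  out <- distance_map(d, source = "model")
  attr(out, "atom") <- atom
  attr(out, "missing") <- missing
  out
}

#' Read a sequence-predicted distance map from a text file
#'
#' The file must hold an L x L whitespace-separated numeric matrix, one row
#' per residue. Small asymmetries (from a real-valued predictor) are
#' symmetrized as (M + t(M))/2; asymmetry beyond `tolerance` is an error.
#'
#' @param path path to the text matrix.
#' @param expected_length required L (error on mismatch); `NULL` accepts any
#'   square matrix.
#' @param tolerance maximum permitted asymmetry and diagonal magnitude in
#'   Angstrom before the file is considered corrupt (default 0.5).
#' @return a [distance_map()] with `source = "predicted"`.
#' @export
read_predicted_map <- function(path, expected_length = NULL, tolerance = 0.5) {
  if (!file.exists(path)) stop(sprintf("predicted map not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  if (n == 0) stop(sprintf("'%s' is empty", path))
  widths <- lengths(toks)
  if (!is.null(expected_length) &&
      (n != expected_length || any(widths != expected_length)))
    stop(sprintf("dimension error: '%s' is %d x %s, expected %d x %d",
                 path, n, paste(unique(widths), collapse = "/"),
                 expected_length, expected_length))
  if (any(widths != n))
    stop(sprintf("dimension error: '%s' has %d rows but row %d has %d columns",
                 path, n, which(widths != n)[1], widths[widths != n][1]))
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("parse error in '%s' at row %d, column %d: '%s' is not numeric",
                   path, i, j, toks[[i]][j]))
    }
    m[i, ] <- v
  }
  asym <- max(abs(m - t(m)))
  if (asym > tolerance)
    stop(sprintf(
      "'%s' asymmetric beyond tolerance (max |M - t(M)| = %.3g > %.3g); file looks corrupt",
      path, asym, tolerance))
  m <- (m + t(m)) / 2
  if (any(abs(diag(m)) > tolerance))
    stop(sprintf("'%s' has non-zero diagonal beyond tolerance", path))
  diag(m) <- 0
  if (any(m < 0)) {
    if (min(m) < -tolerance)
      stop(sprintf("'%s' contains negative distances", path))
    m[m < 0] <- 0
  }
  distance_map(m, source = "predicted")
}

#' Mutual threshold filter on a pair of distance maps
#'
#' Distances above the threshold carry little information about the fold, so
#' they are removed jointly: whenever either `a[i,j]` or `b[i,j]` exceeds the
#' threshold, both entries are set to 0. All other entries are copied
#' unchanged. The operation is idempotent.
#'
#' @param a,b [distance_map()] objects (or numeric matrices) of equal size;
#'   conventionally `a` is the sequence-predicted map and `b` the
#'   model-derived map.
#' @param threshold distance cutoff in Angstrom (default 16).
#' @return an object of class `dmqa_filtered_pair` with elements `a_star`,
#'   `b_star` and `threshold`.
#' @export
apply_threshold_filter <- function(a, b, threshold = 16) {
  am <- as_dist_matrix(a, "a")
  bm <- as_dist_matrix(b, "b")
  if (!is_number(threshold) || threshold <= 0)
    stop("threshold must be a positive number")
  if (!all(dim(am) == dim(bm)))
    stop(sprintf("dimension error: maps are %d x %d and %d x %d",
                 nrow(am), ncol(am), nrow(bm), ncol(bm)))
  drop_mask <- (am > threshold) | (bm > threshold)
  am[drop_mask] <- 0
  bm[drop_mask] <- 0
  structure(list(a_star = am, b_star = bm, threshold = threshold),
            class = "dmqa_filtered_pair")
}

#' Upper-triangular difference map
#'
#' Element-wise subtraction `a_star - b_star` of the filtered maps, with all
#' entries on or below the diagonal set to 0. The resulting matrix `U`
#' carries the residual between expected (sequence-predicted) and realized
#' (model) distances and is the sole network input.
#'
#' @param pair a `dmqa_filtered_pair` from [apply_threshold_filter()].
#' @return object of class `dmqa_diffmap` with elements `values` (L x L,
#'   signed Angstrom residuals, strictly lower triangle and diagonal exactly
#'   0) and `length`.
#' @export
difference_map <- function(pair) {
  if (!inherits(pair, "dmqa_filtered_pair"))
    stop("pair must come from apply_threshold_filter()")
  d <- pair$a_star - pair$b_star
  if (any(!is.finite(d)))
    stop("difference map contains non-finite values; filter the maps first")
  d[lower.tri(d, diag = TRUE)] <- 0
  structure(list(values = d, length = nrow(d)), class = "dmqa_diffmap")
}

#' One decoy with its difference map and (optional) true quality
#'
#' @param target_id,model_id identifiers.
#' @param diff a `dmqa_diffmap`.
#' @param true_gdtts true GDT-TS score in \[0,1\], or `NA` when unknown.
#' @return object of class `dmqa_record`.
#' @export
model_record <- function(target_id, model_id, diff, true_gdtts = NA_real_) {
  stopifnot(is.character(target_id), is.character(model_id),
            inherits(diff, "dmqa_diffmap"))
  if (!is.na(true_gdtts) &&
      (!is.numeric(true_gdtts) || true_gdtts < 0 || true_gdtts > 1))
    stop(sprintf("true_gdtts of %s/%s must lie in [0,1]", target_id, model_id))
  structure(list(target_id = target_id, model_id = model_id,
                 length = diff$length, diff = diff,
                 true_gdtts = as.numeric(true_gdtts)),
            class = "dmqa_record")
}

#' Featurize one structural model
#'
#' Composes [model_distance_map()], [apply_threshold_filter()] and
#' [difference_map()]: the model's representative-atom distance map is
#' compared against the sequence-predicted map under the mutual threshold
#' filter. Deterministic: identical inputs give bit-identical output.
#'
#' @param pdb model coordinates (path / pdb object / matrix), see
#'   [model_distance_map()].
#' @param predicted_map path to a predicted-map text file, or a
#'   [distance_map()].
#' @param threshold mutual filter cutoff in Angstrom (default 16).
#' @param atom representative-atom convention (see [model_distance_map()]).
#' @param target_id,model_id identifiers stored in the record.
#' @param true_gdtts optional true GDT-TS label in \[0,1\].
#' @return a [model_record()]; attributes `threshold` and `atom` record the
#'   featurization convention.
#' @export
featurize_model <- function(pdb, predicted_map, threshold = 16,
                            atom = c("cb", "ca"),
                            target_id = "target", model_id = "model",
                            true_gdtts = NA_real_) {
  atom <- match.arg(atom)
  a <- if (is.character(predicted_map)) read_predicted_map(predicted_map)
       else predicted_map
  if (!inherits(a, "dmqa_distance_map"))
    stop("predicted_map must be a file path or dmqa_distance_map")
  b <- model_distance_map(pdb, length = a$length, atom = atom)
  if (b$length != a$length)
    stop(sprintf("alignment error: model has %d residues, predicted map is %d x %d",
                 b$length, a$length, a$length))
  u <- difference_map(apply_threshold_filter(a, b, threshold))
  rec <- model_record(target_id, model_id, u, true_gdtts)
  attr(rec, "threshold") <- threshold
  attr(rec, "atom") <- atom
  rec
}

#' Write / read a difference-map feature store
#'
#' The store is a single binary container holding each difference map under
#' the key `"{target_id}/{model_id}"` together with its length and the
#' featurization convention (threshold, atom). A companion manifest TSV has
#' columns exactly `target_id, model_id, length, feature_key, true_gdtts`
#' (empty string when the label is unknown).
#'
#' @param records list of [model_record()] objects (all featurized under one
#'   convention).
#' @param path store file path (`.rds`).
#' @param threshold,atom featurization convention recorded in the store.
#' @return `path`, invisibly.
#' @export
write_feature_store <- function(records, path, threshold = 16, atom = "cb") {
  stopifnot(length(records) > 0)
  keys <- vapply(records, function(r) paste(r$target_id, r$model_id, sep = "/"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate target_id/model_id keys in feature store")
  feats <- lapply(records, function(r)
    list(values = r$diff$values, length = r$length,
         true_gdtts = r$true_gdtts))
  names(feats) <- keys
  saveRDS(list(features = feats, threshold = threshold, atom = atom,
               version = 1L), path)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature store not found: '%s'", path))
  store <- readRDS(path)
  if (!is.list(store) || is.null(store$features))
    stop(sprintf("'%s' is not a dmqa feature store", path))
  store
}

# rebuild model records from a store (+ optional label override)
store_records <- function(store) {
  keys <- names(store$features)
  lapply(keys, function(k) {
    f <- store$features[[k]]
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    u <- structure(list(values = f$values, length = f$length),
                   class = "dmqa_diffmap")
    model_record(parts[1], paste(parts[-1], collapse = "/"), u,
                 f$true_gdtts %||% NA_real_)
  })
}

#' @rdname write_feature_store
#' @param manifest_path TSV output path for the manifest.
#' @export
write_feature_manifest <- function(records, manifest_path) {
  df <- data.frame(
    target_id = vapply(records, `[[`, character(1), "target_id"),
    model_id = vapply(records, `[[`, character(1), "model_id"),
    length = vapply(records, `[[`, numeric(1), "length"),
    feature_key = vapply(records, function(r)
      paste(r$target_id, r$model_id, sep = "/"), character(1)),
    true_gdtts = vapply(records, function(r) {
      if (is.na(r$true_gdtts)) "" else format(r$true_gdtts, digits = 10)
    }, character(1)),
    stringsAsFactors = FALSE)
  write.table(df, manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest_path)
}
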