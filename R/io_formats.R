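#' Feature schema for per-decoy energy features
#'
#' The phase-2 regressor consumes 20 per-decoy features: 3 knowledge-based
#' statistical potentials and 17 all-atom score-function terms. The schema
#' fixes their names and order so that score tables, synthetic ensembles and
#' trained models agree on the feature layout.
#'
#' @param knowledge_based Character vector of knowledge-based potential
#'   column names (default: RW, RWplus, dDFIRE).
#' @param rosetta_terms Character vector of the 17 all-atom score-term
#'   column names (default: the REF2015 terms).
#' @return An object of class `feature_schema` with elements
#'   `knowledge_based`, `rosetta_terms`, `names` (the 20 names in order) and
#'   `total`.
#' @export
#' @examples
#' sch <- feature_schema()
#' sch$total
feature_schema <- function(knowledge_based = c("RW", "RWplus", "dDFIRE"),
                           rosetta_terms = c(
                             "fa_atr", "fa_rep", "fa_sol", "fa_intra_sol",
                             "lk_ball_wtd", "fa_intra_rep", "fa_elec",
                             "pro_close", "hbond_sr_bb", "hbond_lr_bb",
                             "hbond_bb_sc", "hbond_sc", "rama_prepro",
                             "omega", "p_aa_pp", "fa_dun", "yhh_planarity")) {
  knowledge_based <- as.character(knowledge_based)
  rosetta_terms <- as.character(rosetta_terms)
  nm <- c(knowledge_based, rosetta_terms)
  if (anyDuplicated(nm)) stop("feature names must be unique")
  structure(list(knowledge_based = knowledge_based,
                 rosetta_terms = rosetta_terms,
                 names = nm,
                 total = length(nm)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", x$total, " features (",
      length(x$knowledge_based), " knowledge-based + ",
      length(x$rosetta_terms), " score terms)\n", sep = "")
  invisible(x)
}

#' Construct a decoy ensemble
#'
#' An ensemble holds every decoy sampled for one target: ids, landscape
#' fitness (total energy), the per-decoy feature vectors, optionally the true
#' lRMSD to the known native (`rmsd_native`), optionally Cα coordinates, and
#' the semantics used to measure pairwise distance between decoys.
#'
#' @param target_id Target identifier.
#' @param decoys Data frame with columns `decoy_id`, `energy`, optionally
#'   `rmsd_native`, plus one column per schema feature.
#' @param schema A [feature_schema()]; feature columns are matched by name
#'   (case-sensitively). Missing feature columns are allowed (features
#'   unset) but must be all-or-none.
#' @param coords Optional numeric matrix (one row per decoy, `3 * n_atoms`
#'   columns, x/y/z interleaved per atom) of Cα coordinates.
#' @param distance_spec One of `"euclidean-on-coords"`,
#'   `"common-frame-rmsd"`, `"precomputed-matrix"`.
#' @param dist_matrix Symmetric non-negative matrix with zero diagonal;
#'   required when `distance_spec = "precomputed-matrix"`.
#' @return Object of class `decoy_ensemble`.
#' @export
decoy_ensemble <- function(target_id, decoys, schema = feature_schema(),
                           coords = NULL,
                           distance_spec = c("euclidean-on-coords",
                                             "common-frame-rmsd",
                                             "precomputed-matrix"),
                           dist_matrix = NULL) {
  distance_spec <- match.arg(distance_spec)
  stopifnot(is.data.frame(decoys))
  if (!all(c("decoy_id", "energy") %in% names(decoys)))
    stop("decoys must have columns decoy_id and energy")
  if (nrow(decoys) < 2) stop("an ensemble needs at least 2 decoys")
  if (anyDuplicated(decoys$decoy_id))
    stop("duplicate decoy_id within ensemble: ",
         decoys$decoy_id[duplicated(decoys$decoy_id)][1])
  have_feats <- schema$names %in% names(decoys)
  if (any(have_feats) && !all(have_feats))
    stop("incomplete feature columns; missing: ",
         paste(schema$names[!have_feats], collapse = ", "))
  if ("rmsd_native" %in% names(decoys) &&
      any(decoys$rmsd_native < 0, na.rm = TRUE))
    stop("rmsd_native must be >= 0")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(decoys))
      stop("coords must have one row per decoy")
    if (ncol(coords) %% 3 != 0)
      stop("coords must have 3 columns per atom")
  }
  if (distance_spec == "precomputed-matrix") {
    if (is.null(dist_matrix)) stop("precomputed-matrix requires dist_matrix")
    dist_matrix <- as.matrix(dist_matrix)
    n <- nrow(decoys)
    if (!all(dim(dist_matrix) == c(n, n)))
      stop("dist_matrix must be ", n, "x", n)
    if (any(dist_matrix < 0) || any(abs(diag(dist_matrix)) > 1e-12) ||
        any(abs(dist_matrix - t(dist_matrix)) > 1e-8))
      stop("dist_matrix must be symmetric, non-negative, zero diagonal")
  }
  mind <- if ("rmsd_native" %in% names(decoys) &&
              !anyNA(decoys$rmsd_native)) min(decoys$rmsd_native) else NULL
  structure(list(target_id = target_id,
                 decoys = decoys,
                 schema = schema,
                 coords = coords,
                 distance_spec = distance_spec,
                 dist_matrix = dist_matrix,
                 native_known = "rmsd_native" %in% names(decoys),
                 min_dist = mind,
                 size = nrow(decoys)),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat("<decoy_ensemble> target ", x$target_id, ": ", x$size, " decoys, ",
      "distance = ", x$distance_spec,
      if (x$native_known) sprintf(", min_dist = %.3f", x$min_dist) else "",
      "\n", sep = "")
  invisible(x)
}

#' Feature matrix of an ensemble
#'
#' @param ensemble A [decoy_ensemble()].
#' @return Numeric matrix, decoys x schema features, columns in schema order.
#' @export
ensemble_features <- function(ensemble) {
  nm <- ensemble$schema$names
  if (!all(nm %in% names(ensemble$decoys)))
    stop("ensemble has no feature columns")
  as.matrix(ensemble$decoys[, nm, drop = FALSE])
}

#' Read a decoy score table
#'
#' Parses a tab-separated score table with a header row. Required columns:
#' `decoy_id`, `energy`. Optional: `rmsd_native` and the 20 schema feature
#' columns, matched by name regardless of column order.
#'
#' @param path Path to a TSV file.
#' @param schema A [feature_schema()].
#' @param distance_spec Distance semantics to record on the ensemble.
#' @param target_id Target id; defaults to the file name without extension.
#' @return A [decoy_ensemble()].
#' @export
read_decoy_table <- function(path, schema = feature_schema(),
                             distance_spec = "euclidean-on-coords",
                             target_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  for (col in c("decoy_id", "energy"))
    if (!col %in% names(df))
      stop("score table is missing required column '", col, "'")
  df$decoy_id <- as.character(df$decoy_id)
  num_cols <- intersect(c("energy", "rmsd_native", schema$names), names(df))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & v != "NA")
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row ", bad[1])
      v <- suppress
    }
    df[[col]] <- v
  }
  keep <- intersect(c("decoy_id", "energy", "rmsd_native", schema$names),
                    names(df))
  decoy_ensemble(target_id = target_id %||% sub("\\.[^.]*$", "", basename(path)),
                 decoys = df[, keep, drop = FALSE], schema = schema,
                 distance_spec = distance_spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a decoy score table
#'
#' Inverse of [read_decoy_table()]: writes `decoy_id`, `energy`,
#' `rmsd_native` (if present) and the schema feature columns as TSV.
#'
#' @param ensemble A [decoy_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decoy_table <- function(ensemble, path) {
  keep <- intersect(c("decoy_id", "energy", "rmsd_native",
                      ensemble$schema$names), names(ensemble$decoys))
  write.table(ensemble$decoys[, keep, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach Cα coordinates from PDB files
#'
#' Reads one PDB file per decoy and attaches the Cα trace (first model,
#' first alternate location, residue order) as ensemble coordinates. All
#' decoys must have the same Cα count.
#'
#' @param paths Character vector of PDB paths; names are decoy ids (defaults
#'   to the file base name without extension).
#' @param ensemble A [decoy_ensemble()] whose decoy ids the files cover.
#' @return The ensemble with `coords` attached.
#' @export
read_ca_coordinates <- function(paths, ensemble) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_ca_coordinates requires the bio3d package")
  ids <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  names(paths) <- ids
  missing <- setdiff(ensemble$decoys$decoy_id, ids)
  if (length(missing))
    stop("no coordinate file for decoy_id: ", missing[1])
  xyz <- lapply(ensemble$decoys$decoy_id, function(id) {
    pdb <- bio3d::read.pdb(paths[[id]], multi = FALSE, verbose = FALSE)
    at <- pdb$atom
    at <- at[at$type == "ATOM" & at$elety == "CA" &
               (is.na(at$alt) | at$alt %in% c("", "A")), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno)), , drop = FALSE]
    as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  })
  lens <- lengths(xyz)
  if (length(unique(lens)) != 1)
    stop("CA count mismatch across decoys: ", min(lens) / 3, " vs ",
         max(lens) / 3)
  ensemble$coords <- do.call(rbind, xyz)
  ensemble
}

#' Write a synthetic Cα-only PDB file
#'
#' Emits minimal ATOM records (CA atoms of poly-alanine) for a flat
#' coordinate vector; intended for fixtures and round-trip tests of
#' [read_ca_coordinates()], not as a structure model.
#'
#' @param xyz Numeric vector, length `3 * n_atoms` (x/y/z per residue).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(xyz, path) {
  stopifnot(length(xyz) %% 3 == 0)
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(m)), seq_len(nrow(m)), m[, 1], m[, 2], m[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read/write a coordinate table (TSV alternative to PDB input)
#'
#' Long-format TSV with columns `decoy_id`, `atom_index`, `x`, `y`, `z`.
#'
#' @param path TSV path.
#' @param ensemble A [decoy_ensemble()] to attach coordinates to.
#' @return `read_coord_table`: the ensemble with `coords` attached.
#' @export
read_coord_table <- function(path, ensemble) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("decoy_id", "atom_index", "x", "y", "z") %in% names(df)))
  ids <- ensemble$decoys$decoy_id
  missing <- setdiff(ids, df$decoy_id)
  if (length(missing)) stop("no coordinates for decoy_id: ", missing[1])
  xyz <- lapply(ids, function(id) {
    d <- df[df$decoy_id == id, , drop = FALSE]
    d <- d[order(d$atom_index), , drop = FALSE]
    as.numeric(t(as.matrix(d[, c("x", "y", "z")])))
  })
  lens <- lengths(xyz)
  if (length(unique(lens)) != 1)
    stop("CA count mismatch across decoys: ", min(lens) / 3, " vs ",
         max(lens) / 3)
  ensemble$coords <- do.call(rbind, xyz)
  ensemble
}

#' @rdname read_coord_table
#' @export
write_coord_table <- function(ensemble, path) {
  if (is.null(ensemble$coords)) stop("ensemble has no coordinates")
  n_at <- ncol(ensemble$coords) / 3
  df <- data.frame(
    decoy_id = rep(ensemble$decoys$decoy_id, each = n_at),
    atom_index = rep(seq_len(n_at), times = ensemble$size),
    x = as.numeric(t(ensemble$coords[, seq(1, by = 3, length.out = n_at)])),
    y = as.numeric(t(ensemble$coords[, seq(2, by = 3, length.out = n_at)])),
    z = as.numeric(t(ensemble$coords[, seq(3, by = 3, length.out = n_at)])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a basin assignment table
#'
#' TSV with columns `decoy_id`, `basin_id`, `is_focal_minimum` (0/1).
#'
#' @param decomp A `basin_decomposition` (see [assign_basins()]).
#' @param ensemble The matching [decoy_ensemble()].
#' @param path File path.
#' @return `read_basin_assignment`: a data frame with the three columns.
#' @export
write_basin_assignment <- function(decomp, ensemble, path) {
  focal <- vapply(decomp$basins, function(b) b$focal_minimum, integer(1))
  df <- data.frame(decoy_id = ensemble$decoys$decoy_id,
                   basin_id = decomp$assignment,
                   is_focal_minimum = as.integer(
                     seq_len(ensemble$size) %in% focal))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_basin_assignment
#' @export
read_basin_assignment <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("decoy_id", "basin_id", "is_focal_minimum") %in% names(df)))
  df$decoy_id <- as.character(df$decoy_id)
  df
}

#' Write a selection/evaluation report as JSON
#'
#' Serializes a selection result, evaluation table or benchmark report to
#' JSON with deterministic key order (the list order of the input), so that
#' identical runs yield byte-identical files.
#'
#' @param result A named list (e.g. a `selection_result` or the output of
#'   [run_benchmark()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  json <- jsonlite::toJSON(strip_classes(result), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

# jsonlite serializes classed lists via asJSON dispatch; flatten to plain
# lists so key order is exactly the construction order.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_classes)
  }
  x
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
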