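# 2D molecular descriptor computation and feature-table assembly.
#
# Descriptors are the union of three 2D families, disambiguated by a
# source prefix: OB_ (OpenBabel physicochemical properties), CMR_
# (ChemmineR atom / ring / functional-group counts) and TOPO_ (graph
# topology, see topology.R). 3D families are never computed: everything
# here derives from the bond graph and composition only, so results do
# not depend on conformer generation. A descriptor whose computation
# fails or is undefined for a molecule is recorded as missing (NA),
# never as zero — such values are missing-not-at-random and downstream
# imputation policies treat them explicitly.

OB_NUMERIC_PROPS <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
CMR_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

coerce_missing <- function(x) {
  nm <- names(x)
  x <- suppressWarnings(as.numeric(x))
  x[!is.finite(x)] <- NA_real_
  names(x) <- nm
  x
}

# Element counts parsed directly from a canonical SMILES string; robust
# for structures (single atoms, ions) that the SDF round trip rejects.
smiles_element_counts <- function(smiles) {
  counts <- stats::setNames(rep(0, length(CMR_ELEMENTS)), CMR_ELEMENTS)
  body <- gsub("\\[([A-Za-z][a-z]?)[^]]*\\]", " \\1 ", smiles)
  toks <- regmatches(body, gregexpr("Cl|Br|Si|Se|[BCNOPSFI]|\\b[bcnops]\\b|[bcnops]", body))[[1]]
  for (t in toks) {
    el <- if (t %in% c("b", "c", "n", "o", "p", "s")) toupper(t) else t
    if (el %in% CMR_ELEMENTS) counts[el] <- counts[el] + 1
  }
  out <- counts
  names(out) <- paste0("COMP_n", CMR_ELEMENTS)
  c(out, COMP_nHalogen = sum(counts[c("F", "Cl", "Br", "I")]))
}

# A parsed SDF molecule is usable when its atom block carries element
# labels; degenerate single-atom structures come back malformed.
sdf_mol_ok <- function(mol) {
  ab <- tryCatch(ChemmineR::atomblock(mol), error = function(e) NULL)
  !is.null(ab) && nrow(ab) > 0 &&
    all(grepl("^[A-Z][a-z]?_[0-9]+$", rownames(ab)))
}

# Descriptor blocks for a batch of molecules given an SDFset; returns a
# list of named numeric vectors (one per molecule).
descriptor_vectors_from_sdf <- function(sdf, smiles = NULL) {
  n <- length(sdf)
  ob <- tryCatch(ChemmineR::propOB(sdf), error = function(e) NULL)
  if (is.null(ob)) {
    # Some structures (e.g. single heavy atoms) abort the whole batch in
    # the backend; retry molecule by molecule so one failure costs one row.
    rows <- lapply(seq_len(n), function(i) {
      r <- tryCatch(ChemmineR::propOB(sdf[i]), error = function(e) NULL)
      if (is.null(r)) stats::setNames(rep(NA_real_, length(OB_NUMERIC_PROPS)),
                                      OB_NUMERIC_PROPS)
      else unlist(r[1, OB_NUMERIC_PROPS])
    })
    ob <- as.data.frame(do.call(rbind, rows))
  }
  rings <- tryCatch(ChemmineR::rings(sdf, upper = 12, type = "count",
                                     arom = TRUE, inner = FALSE),
                    error = function(e) NULL)
  if (!is.null(rings) && is.null(dim(rings))) {
    rings <- matrix(rings, nrow = 1, dimnames = list(NULL, names(rings)))
  }
  grps <- tryCatch(ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA"),
                   error = function(e) NULL)
  grp_names <- if (is.null(grps)) character(0) else colnames(grps)
  lapply(seq_len(n), function(i) {
    mol <- sdf[[i]]
    ok <- sdf_mol_ok(mol)
    comp <- if (is.null(smiles)) NULL else smiles_element_counts(smiles[i])
    ring_i <- if (is.null(rings) || !ok)
      c(CMR_rings = NA_real_, CMR_aromaticRings = NA_real_)
      else c(CMR_rings = coerce_missing(rings[i, "RINGS"]),
             CMR_aromaticRings = coerce_missing(rings[i, "AROMATIC"]))
    grp_i <- if (length(grp_names) == 0) NULL else {
      g <- if (ok) coerce_missing(grps[i, ])
        else rep(NA_real_, length(grp_names))
      stats::setNames(g, paste0("CMR_grp_", grp_names))
    }
    ob_i <- stats::setNames(coerce_missing(unlist(ob[i, OB_NUMERIC_PROPS])),
                            paste0("OB_", OB_NUMERIC_PROPS))
    topo <- if (ok) coerce_missing(topology_descriptors(mol)) else {
      probe <- coerce_missing(topology_descriptors_empty())
      probe
    }
    c(ob_i, comp, ring_i, grp_i, topo)
  })
}

topology_descriptors_empty <- function() {
  nm <- c("nHeavyAtoms", "nBonds", "wiener", "diameter", "radius", "balabanJ",
          "eccConn", "zagreb1", "zagreb2", "randic", paste0("MPC", 2:6),
          "BCUTm_hi", "BCUTm_lo", "BCUTen_hi", "BCUTen_lo")
  stats::setNames(rep(NA_real_, length(nm)), paste0("TOPO_", nm))
}

#' Compute the 2D descriptor vector of one molecule
#'
#' @param smiles a standardized SMILES string (see
#'   [standardize_compound()]); unparseable input is an error here, since
#'   curation is expected upstream.
#' @return Named numeric vector; undefined descriptors are `NA`.
#' @export
compute_descriptor_vector <- function(smiles) {
  std <- standardize_compound(smiles)
  if (!std$ok) stopf("cannot compute descriptors: %s", std$reason)
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(std$smiles, "query")))
  descriptor_vectors_from_sdf(sdf, smiles = std$smiles)[[1]]
}

#' Feature table
#'
#' Compounds-by-descriptors matrix with explicit missing values, a 0/1
#' target vector aligned to rows, and per-column metadata.
#'
#' @param values numeric matrix (rows = compounds) with `NA` as the
#'   missing marker; must have row and column names.
#' @param target 0/1 vector of length `nrow(values)`.
#' @param source_tag per-column provenance; derived from the column-name
#'   prefix when `NULL`.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, target, source_tag = NULL) {
  stopifnot(is.matrix(values), length(target) == nrow(values),
            all(target %in% c(0, 1)))
  if (is.null(rownames(values))) rownames(values) <- make_compound_ids(nrow(values))
  if (is.null(colnames(values))) stopf("feature_table requires column names")
  if (is.null(source_tag)) {
    source_tag <- sub("_.*$", "", colnames(values))
    source_tag[!source_tag %in% c("OB", "COMP", "CMR", "TOPO")] <- "synthetic"
  }
  meta <- data.frame(name = colnames(values), source_tag = source_tag,
                     missing_fraction = colMeans(is.na(values)),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(values = values, target = as.numeric(target),
                 row_ids = rownames(values), column_meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d compounds x %d descriptors (%.1f%% missing), %d/%d bitter/sweet\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values)),
              sum(x$target == 0), sum(x$target == 1)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Rebuild a feature_table after subsetting its matrix.
ft_replace <- function(table, values, target = table$target) {
  tags <- table$column_meta$source_tag[match(colnames(values),
                                             table$column_meta$name)]
  feature_table(values, target, source_tag = tags)
}

#' Subset the columns of a feature table
#'
#' @param table a [feature_table()].
#' @param features character vector of descriptor names to keep.
#' @export
ft_select <- function(table, features) {
  missing <- setdiff(features, colnames(table$values))
  if (length(missing)) stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
  ft_replace(table, table$values[, features, drop = FALSE])
}

#' Build the raw feature table of a curated dataset
#'
#' One row per compound, columns the union of all computed descriptor
#' names in a stable (input-order-invariant) lexicographic order; the
#' target comes from the fixed label encoding (bitter = 0, sweet = 1).
#'
#' @param dataset a curated, standardized [curated_dataset()].
#' @return A [feature_table()].
#' @export
build_feature_table <- function(dataset) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) stopf("cannot build a feature table from an empty dataset")
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(rec$smiles, rec$id)))
  vecs <- descriptor_vectors_from_sdf(sdf, smiles = rec$smiles)
  cols <- sort(unique(unlist(lapply(vecs, names))))
  values <- matrix(NA_real_, nrow(rec), length(cols),
                   dimnames = list(rec$id, cols))
  for (i in seq_along(vecs)) values[i, names(vecs[[i]])] <- vecs[[i]]
  feature_table(values, rec$label)
}

#' Write / read a feature table as CSV plus a JSON sidecar
#'
#' Missing values are written as empty cells; the sidecar carries the
#' column metadata and the target vector.
#'
#' @param table a [feature_table()].
#' @param csv_path,meta_path output paths.
#' @export
write_feature_table <- function(table, csv_path, meta_path = NULL) {
  df <- data.frame(id = table$row_ids, target = table$target,
                   table$values, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  if (!is.null(meta_path)) {
    jsonlite::write_json(table$column_meta, meta_path, digits = NA)
  }
  invisible(csv_path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(csv_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  stopifnot(all(c("id", "target") %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), c("id", "target")), drop = FALSE])
  rownames(vals) <- df$id
  feature_table(vals, df$target)
}
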