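# Reading, standardizing and deduplicating SMILES-labelled compound sets.
#
# The curation contract: every retained record carries a canonical,
# salt-stripped parent SMILES, a taste label in {bitter, sweet}, and no two
# records share the same standardized structure. Structure handling is
# delegated to the OpenBabel backend (via ChemmineOB); only its observable
# guarantees (canonicalization, parse checking) are relied upon.

TASTE_LEVELS <- c("bitter", "sweet")
LABEL_ENCODING <- c(bitter = 0, sweet = 1)

#' Curated compound dataset
#'
#' Container for SMILES-labelled compounds. Taste labels are encoded
#' bitter = 0, sweet = 1 throughout the package.
#'
#' @param records data.frame with columns `id`, `smiles`, `taste`, `source`.
#' @return An object of class `curated_dataset`.
#' @export
curated_dataset <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "smiles", "taste", "source") %in% names(records)))
  bad <- !records$taste %in% TASTE_LEVELS
  if (any(bad)) {
    stopf("invalid taste label(s) %s at row(s) %s",
          paste(unique(records$taste[bad]), collapse = ", "),
          paste(which(bad), collapse = ", "))
  }
  records$label <- unname(LABEL_ENCODING[records$taste])
  rownames(records) <- NULL
  structure(list(records = records, label_encoding = LABEL_ENCODING),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<curated_dataset> %d compounds (%d bitter, %d sweet)\n",
              n, sum(x$records$taste == "bitter"),
              sum(x$records$taste == "sweet")))
  invisible(x)
}

#' @export
length.curated_dataset <- function(x) nrow(x$records)

#' Read a compound table from CSV or .smi
#'
#' CSV files must have a header with (configurable) SMILES and taste
#' columns; `.smi` files are whitespace-delimited `SMILES label [id]`
#' lines. Records are returned in file order, unvalidated (SMILES are not
#' yet parsed or standardized). Unknown taste labels are rejected with the
#' offending row number.
#'
#' @param path input file.
#' @param format `"csv"` or `"smi"`; guessed from the extension by default.
#' @param smiles_col,taste_col,id_col CSV column names (`id_col` optional).
#' @return A [curated_dataset()] of raw records.
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "smi"),
                                smiles_col = "smiles", taste_col = "taste",
                                id_col = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.smi$", path, ignore.case = TRUE)) "smi" else "csv"
  }
  if (!file.exists(path)) stopf("cannot read compound table: '%s' not found", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    for (col in c(smiles_col, taste_col)) {
      if (!col %in% names(df)) stopf("column '%s' not found in %s", col, path)
    }
    smiles <- as.character(df[[smiles_col]])
    taste <- trimws(tolower(as.character(df[[taste_col]])))
    ids <- if (!is.null(id_col) && id_col %in% names(df))
      as.character(df[[id_col]]) else make_compound_ids(nrow(df))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    if (any(lengths(parts) < 2)) {
      stopf(".smi line(s) %s lack a taste label",
            paste(which(lengths(parts) < 2), collapse = ", "))
    }
    smiles <- vapply(parts, `[[`, "", 1L)
    taste <- tolower(vapply(parts, `[[`, "", 2L))
    ids <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_, "")
    if (anyNA(ids)) ids <- make_compound_ids(length(smiles))
  }
  bad <- !taste %in% TASTE_LEVELS
  if (any(bad)) {
    stopf("unknown taste label(s) %s at row(s) %s of %s",
          paste(sQuote(unique(taste[bad])), collapse = ", "),
          paste(which(bad), collapse = ", "), path)
  }
  curated_dataset(data.frame(id = ids, smiles = smiles, taste = taste,
                             source = basename(path),
                             stringsAsFactors = FALSE))
}

# Canonicalize one SMILES through OpenBabel; "" signals a parse failure.
ob_canonical <- function(smiles) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  out <- sub("\t.*$", "", sub("\n$", "", out))
  trimws(out)
}

# Heavy-atom count of a single-fragment SMILES (crude token count; used
# only to rank fragments of the same molecule, never as a descriptor).
fragment_heavy_atoms <- function(frag) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(frag)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(0L)
  nrow(ChemmineR::atomblock(sdf[[1]]))
}

#' Standardize a SMILES string
#'
#' Canonicalizes through the cheminformatics backend and strips salt /
#' solvent fragments, keeping the parent fragment (most heavy atoms;
#' carbon-containing fragments preferred; ties broken by longer then
#' lexicographically smaller SMILES). Two spellings of the same structure
#' map to the same output, and the operation is idempotent. Unparseable
#' input yields a rejection, not an error, so callers can log and drop.
#'
#' @param smiles a single SMILES string.
#' @return list with `ok` (logical), `smiles` (standardized string or
#'   `NA`), and `reason` (`NA` or a rejection reason).
#' @export
standardize_compound <- function(smiles) {
  reject <- function(reason) list(ok = FALSE, smiles = NA_character_, reason = reason)
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(reject("empty or non-string SMILES"))
  }
  can <- ob_canonical(smiles)
  if (!nzchar(can)) return(reject("SMILES failed to parse"))
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1) {
    heavy <- vapply(frags, fragment_heavy_atoms, integer(1))
    has_c <- grepl("[Cc]", gsub("\\[[^]]*\\]", "", frags)) |
      grepl("\\[C", frags)
    ord <- order(-has_c, -heavy, -nchar(frags), frags)
    can <- ob_canonical(frags[ord[1]])
    if (!nzchar(can)) return(reject("parent fragment failed to re-parse"))
  }
  list(ok = TRUE, smiles = can, reason = NA_character_)
}

#' Standardize every record of a dataset
#'
#' Applies [standardize_compound()] to each record, dropping rejected
#' SMILES (the rejections are reported, mirroring curation pipelines that
#' remove compounds with incorrect structures).
#'
#' @param dataset a [curated_dataset()].
#' @return list with `dataset` (standardized records) and `rejected`
#'   (data.frame of dropped rows with reasons).
#' @export
standardize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  std <- lapply(rec$smiles, standardize_compound)
  ok <- vapply(std, `[[`, logical(1), "ok")
  rec$smiles[ok] <- vapply(std[ok], `[[`, character(1), "smiles")
  rejected <- data.frame(id = rec$id[!ok], smiles = rec$smiles[!ok],
                         reason = vapply(std[!ok], `[[`, character(1), "reason"),
                         stringsAsFactors = FALSE)
  list(dataset = curated_dataset(rec[ok, , drop = FALSE]), rejected = rejected)
}

#' Deduplicate standardized compounds
#'
#' Groups records by standardized SMILES. A group whose members agree on
#' the taste label keeps its first occurrence; a group with conflicting
#' labels is removed entirely (ambiguous structures carry no information
#' for a binary taste model). Order of the kept representatives follows
#' input order.
#'
#' @param dataset a standardized [curated_dataset()].
#' @return list with `dataset` and `report` (kept / collapsed / removed
#'   counts and the removed ids).
#' @export
deduplicate_compounds <- function(dataset) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  grp <- split(seq_len(nrow(rec)), rec$smiles)
  keep <- integer(0)
  removed <- integer(0)
  n_conflict_groups <- 0L
  n_collapsed_groups <- 0L
  for (idx in grp) {
    labs <- unique(rec$taste[idx])
    if (length(labs) > 1) {
      removed <- c(removed, idx)
      n_conflict_groups <- n_conflict_groups + 1L
    } else {
      keep <- c(keep, idx[1])
      if (length(idx) > 1) n_collapsed_groups <- n_collapsed_groups + 1L
    }
  }
  keep <- sort(keep)
  report <- list(
    n_in = nrow(rec),
    n_kept = length(keep),
    n_collapsed_groups = n_collapsed_groups,
    n_removed_conflicting = length(removed),
    n_conflict_groups = n_conflict_groups,
    removed_ids = rec$id[sort(removed)]
  )
  list(dataset = curated_dataset(rec[keep, , drop = FALSE]), report = report)
}

#' Full curation pipeline
#'
#' Standardize then deduplicate, collecting a single curation report.
#'
#' @param dataset raw [curated_dataset()] from [read_compound_table()].
#' @return list with `dataset` and `report`.
#' @export
curate_compounds <- function(dataset) {
  std <- standardize_dataset(dataset)
  dd <- deduplicate_compounds(std$dataset)
  report <- c(list(n_input = nrow(dataset$records),
                   n_rejected_smiles = nrow(std$rejected),
                   rejected = std$rejected), dd$report)
  list(dataset = dd$dataset, report = report)
}

#' Write a curated dataset and its report
#'
#' @param curated result of [curate_compounds()] (or a bare dataset).
#' @param csv_path output CSV (`id, smiles_standardized, taste, label`).
#' @param report_path optional JSON report path.
#' @export
write_curated <- function(curated, csv_path, report_path = NULL) {
  ds <- if (inherits(curated, "curated_dataset")) curated else curated$dataset
  rec <- ds$records
  out <- data.frame(id = rec$id, smiles_standardized = rec$smiles,
                    taste = rec$taste, label = rec$label)
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(report_path) && !inherits(curated, "curated_dataset")) {
    jsonlite::write_json(curated$report, report_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(csv_path)
}
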