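# Affinity-dataset containers and on-disk formats.
#
# The canonical on-disk layout is plain text: drugs.csv (id,smiles),
# proteins.csv (id,sequence), affinities.csv (drug_id,protein_id,value) and
# an optional folds.json. A reader for the DeepDTA-style benchmark layout
# (JSON ligand/protein tables plus a dense affinity matrix with NaN for
# unmeasured cells) is also provided; that layout is read but never written.

#' Construct an affinity dataset
#'
#' Bundles a drug table, a protein table and the measured (drug, protein,
#' affinity) triples into one validated object. Sparse datasets simply omit
#' unmeasured pairs from `triples`; a dense dataset has exactly
#' `length(drugs) * length(proteins)` triples.
#'
#' @param drugs Named character vector: drug id -> SMILES string. Isomeric
#'   SMILES are accepted verbatim; no canonicalization is applied.
#' @param proteins Named character vector: protein id -> amino-acid string.
#' @param triples Data frame with columns `drug_id`, `protein_id`,
#'   `affinity` (finite numeric).
#' @param folds Optional integer vector, one per triple: 0 marks the
#'   held-out test split, 1..k the cross-validation training folds.
#' @return An object of class `"affinity_dataset"`.
#' @export
affinity_dataset <- function(drugs, proteins, triples, folds = NULL) {
  if (is.null(names(drugs)) || is.null(names(proteins))) {
    stop("`drugs` and `proteins` must be named character vectors", call. = FALSE)
  }
  req <- c("drug_id", "protein_id", "affinity")
  if (!all(req %in% names(triples))) {
    stop("`triples` needs columns drug_id, protein_id, affinity", call. = FALSE)
  }
  triples <- as.data.frame(triples)[req]
  triples$drug_id <- as.character(triples$drug_id)
  triples$protein_id <- as.character(triples$protein_id)
  triples$affinity <- as.numeric(triples$affinity)
  bad_d <- setdiff(triples$drug_id, names(drugs))
  bad_p <- setdiff(triples$protein_id, names(proteins))
  if (length(bad_d) > 0L) {
    stop("triples reference unknown drug ids: ",
         paste(utils::head(bad_d, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(bad_p) > 0L) {
    stop("triples reference unknown protein ids: ",
         paste(utils::head(bad_p, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(triples$affinity))) {
    stop("all affinities must be finite; drop unmeasured pairs instead",
         call. = FALSE)
  }
  if (!is.null(folds)) {
    folds <- as.integer(folds)
    if (length(folds) != nrow(triples) || anyNA(folds) || any(folds < 0L)) {
      stop("`folds` must give one non-negative label per triple", call. = FALSE)
    }
  }
  structure(
    list(drugs = drugs, proteins = proteins, triples = triples, folds = folds),
    class = "affinity_dataset"
  )
}

#' @export
print.affinity_dataset <- function(x, ...) {
  dense <- nrow(x$triples) == length(x$drugs) * length(x$proteins)
  cat("Affinity dataset:", length(x$drugs), "drugs x", length(x$proteins),
      "proteins,", nrow(x$triples),
      if (dense) "triples (dense)\n" else "triples (sparse)\n")
  cat("  affinity range: [", format(min(x$triples$affinity), digits = 4), ", ",
      format(max(x$triples$affinity), digits = 4), "]\n", sep = "")
  if (!is.null(x$folds)) {
    k <- max(x$folds)
    cat("  folds: ", sum(x$folds == 0L), " test, ",
        k, " train folds of sizes ",
        paste(tabulate(x$folds, nbins = k), collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Test whether a dataset is dense
#'
#' A dense dataset measures every drug-protein combination, so the number of
#' triples equals the drug count times the protein count.
#'
#' @param d An `"affinity_dataset"`.
#' @return Logical.
#' @export
is_dense <- function(d) {
  stopifnot(inherits(d, "affinity_dataset"))
  nrow(d$triples) == length(d$drugs) * length(d$proteins)
}

#' Read an affinity dataset from disk
#'
#' `format = "csv"` reads the canonical layout written by
#' [write_affinity_dataset()]: `drugs.csv`, `proteins.csv`,
#' `affinities.csv` and, if present, `folds.json`. `format = "deepdta"`
#' reads a benchmark-style directory: `ligands_can.txt` and `proteins.txt`
#' (JSON objects mapping id -> sequence) and `Y.txt` (whitespace-separated
#' dense affinity matrix, drugs in rows, `NaN`/`NA` for unmeasured cells);
#' matrix cells that are missing are omitted from the triples.
#'
#' @param path Directory containing the dataset files.
#' @param format `"csv"` or `"deepdta"`.
#' @param affinity_transform `"none"`, or `"pkd"` to convert raw Kd values
#'   in nM into log space via [kd_to_pkd()] (the usual treatment of the
#'   Davis kinase data).
#' @return An `"affinity_dataset"`.
#' @export
read_affinity_dataset <- function(path, format = c("csv", "deepdta"),
                                  affinity_transform = c("none", "pkd")) {
  format <- match.arg(format)
  affinity_transform <- match.arg(affinity_transform)
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  d <- switch(format,
    csv = read_dataset_csv(path),
    deepdta = read_dataset_deepdta(path)
  )
  if (affinity_transform == "pkd") {
    d$triples$affinity <- kd_to_pkd(d$triples$affinity)
  }
  d
}

read_dataset_csv <- function(path) {
  need <- file.path(path, c("drugs.csv", "proteins.csv", "affinities.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop("missing dataset files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  dr <- utils::read.csv(need[1L], colClasses = "character")
  pr <- utils::read.csv(need[2L], colClasses = "character")
  af <- utils::read.csv(need[3L])
  if (!all(c("id", "smiles") %in% names(dr))) {
    stop("drugs.csv needs columns id,smiles", call. = FALSE)
  }
  if (!all(c("id", "sequence") %in% names(pr))) {
    stop("proteins.csv needs columns id,sequence", call. = FALSE)
  }
  if (!is.numeric(af$value)) {
    stop("affinities.csv column `value` must be numeric", call. = FALSE)
  }
  drugs <- stats::setNames(dr$smiles, dr$id)
  proteins <- stats::setNames(pr$sequence, pr$id)
  triples <- data.frame(drug_id = as.character(af$drug_id),
                        protein_id = as.character(af$protein_id),
                        affinity = af$value)
  folds <- NULL
  fold_file <- file.path(path, "folds.json")
  if (file.exists(fold_file)) {
    lab <- unlist(jsonlite::read_json(fold_file)$labels)
    folds <- ifelse(lab == "test", 0L, suppressWarnings(as.integer(lab)))
    if (anyNA(folds)) stop("unparseable fold labels in folds.json", call. = FALSE)
  }
  affinity_dataset(drugs, proteins, triples, folds)
}

read_dataset_deepdta <- function(path) {
  lig <- file.path(path, "ligands_can.txt")
  prt <- file.path(path, "proteins.txt")
  ymat <- file.path(path, "Y.txt")
  missing <- c(lig, prt, ymat)[!file.exists(c(lig, prt, ymat))]
  if (length(missing) > 0L) {
    stop("missing dataset files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  drugs <- unlist(jsonlite::read_json(lig))
  proteins <- unlist(jsonlite::read_json(prt))
  y <- as.matrix(utils::read.table(ymat, na.strings = c("NA", "NaN", "nan")))
  if (nrow(y) != length(drugs) || ncol(y) != length(proteins)) {
    stop("Y.txt is ", nrow(y), "x", ncol(y), " but tables give ",
         length(drugs), " drugs and ", length(proteins), " proteins",
         call. = FALSE)
  }
  keep <- which(!is.na(y), arr.ind = TRUE)
  triples <- data.frame(
    drug_id = names(drugs)[keep[, 1L]],
    protein_id = names(proteins)[keep[, 2L]],
    affinity = y[keep]
  )
  affinity_dataset(drugs, proteins, triples)
}

#' Write an affinity dataset in the canonical CSV/JSON layout
#'
#' @param d An `"affinity_dataset"`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_affinity_dataset <- function(d, path) {
  stopifnot(inherits(d, "affinity_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(id = names(d$drugs), smiles = unname(d$drugs)),
                   file.path(path, "drugs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = names(d$proteins),
                              sequence = unname(d$proteins)),
                   file.path(path, "proteins.csv"), row.names = FALSE)
  utils::write.csv(data.frame(drug_id = d$triples$drug_id,
                              protein_id = d$triples$protein_id,
                              value = d$triples$affinity),
                   file.path(path, "affinities.csv"), row.names = FALSE)
  if (!is.null(d$folds)) {
    lab <- ifelse(d$folds == 0L, "test", as.character(d$folds))
    jsonlite::write_json(list(k = max(d$folds), labels = as.list(lab)),
                         file.path(path, "folds.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Assign cross-validation folds
#'
#' Randomly holds out `test_fraction` of the triples as a fixed test split
#' and partitions the remainder into `k` folds of near-equal size. The
#' assignment is exhaustive, disjoint and fully determined by `seed`.
#'
#' @param d An `"affinity_dataset"`.
#' @param k Number of training folds (default 5).
#' @param test_fraction Fraction held out as the test split (default 1/6,
#'   the usual benchmark protocol).
#' @param seed Integer seed.
#' @return The dataset with its `folds` field populated (0 = test, 1..k =
#'   training folds).
#' @export
split_folds <- function(d, k = 5L, test_fraction = 1 / 6, seed = 1L) {
  stopifnot(inherits(d, "affinity_dataset"))
  k <- as.integer(k)
  n <- nrow(d$triples)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_test <- round(n * test_fraction)
  if (n - n_test < k) {
    stop("not enough triples (", n, ") for ", k, " folds plus a test split",
         call. = FALSE)
  }
  folds <- integer(n)
  with_seed(seed, {
    perm <- sample.int(n)
    folds[perm[seq_len(n_test)]] <- 0L
    train_idx <- perm[(n_test + 1L):n]
    folds[train_idx] <- rep_len(seq_len(k), length(train_idx))
  })
  d$folds <- folds
  d
}
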