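# Readers/writers: FASTA in, label tables in, tensor containers and metric
# reports out.

#' Read a FASTA file of genome sequences
#'
#' Accepts multi-record, line-wrapped, case-insensitive FASTA; residues are
#' uppercased and record order is preserved. IUPAC ambiguity codes are kept
#' (featurization skips windows containing them).
#'
#' @param path FASTA file.
#' @param concatenate treat all records as fragments of one genome and
#'   concatenate them into a single sequence named after the first record
#'   (by default each record is featurized separately).
#' @return Named character vector of uppercased sequences.
#' @export
read_fasta <- function(path, concatenate = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  xs <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e)
                   stop("failed to parse FASTA '", path, "': ",
                        conditionMessage(e)))
  if (length(xs) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(xs))   # first header token
  seqs <- stats::setNames(toupper(as.character(xs)), ids)
  if (any(!nzchar(seqs))) stop("FASTA file contains an empty record")
  if (concatenate)
    seqs <- stats::setNames(paste(seqs, collapse = ""), ids[1])
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence IDs in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Read a sequence-to-taxon label table
#'
#' Two-column tab-separated text (no header): sequence ID, taxon name at one
#' taxonomy level. IDs must be unique and taxon names non-empty.
#'
#' @param path label file.
#' @param sequence_ids optional vector of known sequence IDs; labels without
#'   a sequence, and sequences without a label, produce warnings (not
#'   errors).
#' @return Named character vector mapping sequence ID to taxon.
#' @export
read_labels <- function(path, sequence_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("label table must have two tab-separated columns")
  ids <- df[[1]]; taxa <- df[[2]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence IDs in label table: ",
         paste(dup, collapse = ", "))
  if (any(!nzchar(taxa))) stop("label table contains empty taxon names")
  out <- stats::setNames(taxa, ids)
  if (!is.null(sequence_ids)) {
    extra <- setdiff(ids, sequence_ids)
    missing <- setdiff(sequence_ids, ids)
    if (length(extra))
      warning("labels for unknown sequences: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ...")
    if (length(missing))
      warning("sequences without labels: ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ...")
  }
  out
}

#' Tensor container: write and reload featurized datasets
#'
#' One container file per dataset (an RDS holding the tensors keyed by
#' sequence ID) plus a JSON sidecar recording k, the corner assignment and
#' the normalization flag, so downstream steps are self-describing. The
#' round trip is bit-identical.
#'
#' @param tensors named list of `cgr_tensor` objects sharing one k.
#' @param path container path (conventionally `.rds`); the sidecar is
#'   written next to it as `<path>.json`.
#' @return `write_tensor_store()`: the path, invisibly.
#'   `read_tensor_store()`: the named list of tensors, with the sidecar
#'   metadata attached as attribute `meta`.
#' @export
write_tensor_store <- function(tensors, path) {
  stopifnot(is.list(tensors), length(tensors) >= 1L)
  ks <- unique(vapply(tensors, function(t) attr(t, "k"), integer(1)))
  if (length(ks) != 1L) stop("all tensors must share the same k")
  corners <- attr(tensors[[1]], "corners")
  meta <- list(k = ks,
               corners = stats::setNames(
                 lapply(rownames(corners), function(n) unname(corners[n, ])),
                 rownames(corners)),
               normalized = isTRUE(attr(tensors[[1]], "normalized")),
               ids = names(tensors))
  saveRDS(tensors, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tensor_store
#' @export
read_tensor_store <- function(path) {
  tensors <- readRDS(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(tensors, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tensors
}

#' Write a metric report as JSON and a confusion matrix as TSV
#'
#' @param report a [metric_report()] result.
#' @param json_path metrics output (JSON); the confusion matrix goes to
#'   `cm_path` as a tab-separated grid with taxon names on both axes.
#' @param cm_path optional confusion-matrix TSV path.
#' @return `json_path`, invisibly.
#' @export
write_metric_report <- function(report, json_path, cm_path = NULL) {
  out <- report[c("accuracy", "macro_precision", "macro_recall", "macro_f1")]
  out$top_k <- as.list(report$top_k)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cm_path)) {
    cm <- report$confusion
    utils::write.table(cbind(true = rownames(cm), as.data.frame(unclass(cm))),
                       cm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
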