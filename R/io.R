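#' Read a nucleotide alignment
#'
#' FASTA or NEXUS, case-insensitive, with RNA `U` normalized to `T`.
#' Sequences must be aligned (equal length) and labels unique.
#'
#' @param path file path.
#' @param format `"fasta"` or `"nexus"` (default: guessed from the
#'   extension, falling back to fasta).
#' @return alignment of class `phyDat`.
#' @export
readAlignment <- function(path, format = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "fasta"
  format <- match.arg(format, c("fasta", "nexus"))
  seqs <- if (format == "fasta") {
    x <- tryCatch(seqinr::read.fasta(path, as.string = TRUE, seqtype = "AA",
                                     forceDNAtolower = FALSE),
                  error = function(e) stop("empty or unparseable alignment file: ",
                                           path))
    if (length(x) == 0) stop("empty alignment file: ", path)
    lapply(x, function(s) as.character(s)[1])
  } else {
    x <- ape::read.nexus.data(path)
    if (length(x) == 0) stop("empty alignment file: ", path)
    lapply(x, paste0, collapse = "")
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  lens <- vapply(seqs, nchar, 0L)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[lens != lens[1]]
    stop("sequences are not aligned (ragged lengths), first offender: ", bad[1])
  }
  mat <- do.call(rbind, lapply(seqs, function(s) {
    ch <- tolower(strsplit(s, "")[[1]])
    ch[ch == "u"] <- "t"
    ch
  }))
  rownames(mat) <- names(seqs)
  phangorn::phyDat(mat, type = "DNA")
}

#' Write a nucleotide alignment
#'
#' @param aln `phyDat` alignment.
#' @param path output file.
#' @param format `"fasta"` or `"nexus"`.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  ch <- as.character(aln)
  if (format == "fasta") {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(ch))) {
      writeLines(paste0(">", rownames(ch)[i]), con)
      writeLines(paste0(ch[i, ], collapse = ""), con)
    }
  } else {
    lst <- setNames(lapply(seq_len(nrow(ch)), function(i) ch[i, ]), rownames(ch))
    ape::write.nexus.data(lst, file = path, interleaved = FALSE)
  }
  invisible(path)
}

#' Read / write phylogenetic trees
#'
#' Newick or NEXUS trees via the standard parsers. Unrooted trees are
#' serialized with an arbitrary trifurcating root; a write/read round trip
#' preserves splits and branch lengths.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"` (default: guessed from extension).
#' @return `readTree`: a `phylo`.
#' @export
readTree <- function(path, format = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "newick"
  format <- match.arg(format, c("newick", "nexus"))
  tr <- tryCatch(
    if (format == "newick") ape::read.tree(path) else ape::read.nexus(path),
    error = function(e) stop("failed to parse ", format, " tree in ", path,
                             ": ", conditionMessage(e)))
  if (is.null(tr)) stop("failed to parse ", format, " tree in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  tr
}

#' @param tree `phylo` or `softNJTree`.
#' @rdname readTree
#' @export
writeTree <- function(tree, path, format = NULL) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (is.null(format))
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "newick"
  format <- match.arg(format, c("newick", "nexus"))
  if (format == "newick") ape::write.tree(tree, file = path)
  else ape::write.nexus(tree, file = path)
  invisible(path)
}
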