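#' Aligned viral sequences
#'
#' `sigma_alignment()` builds the container every analysis in the package
#' operates on: a set of equal-length, pre-aligned nucleotide sequences over
#' the alphabet `A, C, G, T, -, N`, together with a declared strand sense.
#' Sigma viruses are negative-sense RNA viruses, so the same alignment can
#' represent the genome (negative sense), the antigenome, or the mRNA-sense
#' product of Sanger sequencing; the ADAR analysis needs to know which
#' convention the stored characters follow.
#'
#' @param ids Character vector of unique sample identifiers.
#' @param seqs Character vector of sequences, all the same length, uppercase
#'   or lowercase; `U` is normalised to `T`.
#' @param sense One of `"mrna"` (default), `"genome"`, `"antigenome"`: the
#'   strand convention of the stored characters.
#'
#' @return An object of class `sigma_alignment`: a list with elements `id`,
#'   `seq` and `sense`.
#' @examples
#' aln <- sigma_alignment(c("a", "b"), c("ACGT", "ACGA"))
#' n_seq(aln)
#' n_sites(aln)
#' @export
sigma_alignment <- function(ids, seqs, sense = c("mrna", "genome", "antigenome")) {
  sense <- match.arg(sense)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (length(ids) != length(seqs))
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  if (length(seqs) == 0) stop("alignment has no sequences", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1], call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("unequal sequence lengths: id '", ids[which(lens != lens[1])[1]],
         "' has length ", lens[lens != lens[1]][1], ", expected ", lens[1],
         call. = FALSE)
  if (lens[1] == 0) stop("sequences have zero length", call. = FALSE)
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in sequence '", ids[i], "' at position ", bad[i], call. = FALSE)
  }
  structure(list(id = ids, seq = seqs, sense = sense),
            class = "sigma_alignment")
}

#' @rdname sigma_alignment
#' @param x A `sigma_alignment`.
#' @export
n_seq <- function(x) length(x$id)

#' @rdname sigma_alignment
#' @export
n_sites <- function(x) nchar(x$seq[1])

#' @export
print.sigma_alignment <- function(x, ...) {
  cat("<sigma_alignment> ", n_seq(x), " sequences x ", n_sites(x),
      " sites (sense: ", x$sense, ")\n", sep = "")
  invisible(x)
}

# character matrix view (n x L), rownames = ids
aln_matrix <- function(x) {
  m <- matrix(unlist(strsplit(x$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = length(x$seq), byrow = TRUE)
  rownames(m) <- x$id
  m
}

# integer coding A,C,G,T,-,N -> 0..5 for the compiled distance kernel
aln_int_matrix <- function(x) {
  m <- aln_matrix(x)
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L, `-` = 4L, N = 5L)
  im <- matrix(codes[m], nrow = nrow(m))
  rownames(im) <- x$id
  im
}

# rebuild an alignment from a character matrix, keeping ids and sense
aln_from_matrix <- function(m, sense) {
  sigma_alignment(rownames(m), apply(m, 1, paste0, collapse = ""), sense)
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned nucleotide FASTA into a [sigma_alignment()]. Lowercase
#' is normalised to uppercase and `U` to `T`; records must all have the same
#' length and ids (the first whitespace-delimited token of each header) must
#' be unique.
#'
#' @param path Path to a FASTA file.
#' @inheritParams sigma_alignment
#' @return A [sigma_alignment()].
#' @export
read_fasta_alignment <- function(path, sense = c("mrna", "genome", "antigenome")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  sigma_alignment(ids, as.character(set), sense = match.arg(sense))
}

#' Write an alignment to FASTA
#'
#' @param x A [sigma_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(x, path) {
  stopifnot(inherits(x, "sigma_alignment"))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a tab-separated metadata table with mandatory columns `sample_id`
#' and `population` and optional `latitude`, `longitude` and `year` columns.
#' Extra columns are carried along untouched.
#'
#' @param path Path to a TSV file.
#' @param alignment Optional [sigma_alignment()]; ids present in the metadata
#'   but absent from the alignment are reported as a warning (not an error),
#'   since metadata tables often cover more samples than were sequenced.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path, alignment = NULL) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sample_id", "population"))
    if (!col %in% names(md))
      stop("metadata is missing mandatory column '", col, "'", call. = FALSE)
  md$sample_id <- as.character(md$sample_id)
  md$population <- as.character(md$population)
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1], call. = FALSE)
  if (any(is.na(md$population) | md$population == ""))
    stop("empty population label for sample ",
         md$sample_id[which(is.na(md$population) | md$population == "")[1]],
         call. = FALSE)
  if (!is.null(alignment)) {
    extra <- setdiff(md$sample_id, alignment$id)
    if (length(extra) > 0)
      warning(length(extra), " metadata id(s) not present in the alignment: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ..." else "", call. = FALSE)
  }
  tibble::as_tibble(md)
}

#' Collapse identical sequences into haplotypes
#'
#' Groups sequences that are character-for-character identical (gaps and `N`s
#' compared literally) into haplotypes, the grouping used to size the nodes
#' of a haplotype network. Rows are ordered by total count (decreasing), ties
#' broken by the first member id.
#'
#' @param alignment A [sigma_alignment()].
#' @param metadata Optional tibble with `sample_id` and `population` columns;
#'   when supplied, one count column per population is added.
#' @return A tibble with columns `haplotype` (integer rank), `sequence`, `n`,
#'   `members` (list column of ids) and, with metadata, one column per
#'   population.
#' @export
collapse_haplotypes <- function(alignment, metadata = NULL) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  grp <- split(seq_along(alignment$seq), alignment$seq)
  first_pos <- vapply(grp, min, integer(1))
  counts <- lengths(grp)
  ord <- order(-counts, first_pos)
  grp <- grp[ord]
  out <- tibble::tibble(
    haplotype = seq_along(grp),
    sequence = names(grp),
    n = unname(lengths(grp)),
    members = unname(lapply(grp, function(i) alignment$id[i]))
  )
  if (!is.null(metadata)) {
    pop <- setNames(metadata$population, metadata$sample_id)
    missing_ids <- setdiff(alignment$id, metadata$sample_id)
    if (length(missing_ids) > 0)
      stop("no population label for sample(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
    pops <- sort(unique(pop[alignment$id]))
    for (p in pops)
      out[[p]] <- vapply(out$members,
                         function(ids) sum(pop[ids] == p), integer(1))
  }
  out
}
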