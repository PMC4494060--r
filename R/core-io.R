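## Data model and readers/writers shared by every analysis stage.
##
## Internal coordinate convention: 0-based, half-open, forward strand.
## GFF3/TSV input (1-based inclusive) is converted on read and back on write.
## Genes may wrap the circular origin of the coordinate system; they are
## stored with start > end and `wraps = TRUE`.

#' Circular genome object
#'
#' A circular bacterial chromosome with annotated replication origin (ori)
#' and terminus (ter). Positions are 0-based and normalized modulo the genome
#' length.
#'
#' @param id genome identifier.
#' @param length genome length in bp (> 0).
#' @param ori,ter integer positions of the origin and terminus of
#'   replication; normalized modulo `length`; must differ after
#'   normalization.
#' @param sequence optional DNA string over A, C, G, T, N whose number of
#'   characters must equal `length`.
#' @return an object of class `circular_genome` with fields `id`, `length`,
#'   `ori`, `ter` and optionally `sequence`.
#' @export
circular_genome <- function(id, length, ori, ter, sequence = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop_arch("genome length must be > 0")
  ori <- as.integer(pmod(ori, length))
  ter <- as.integer(pmod(ter, length))
  if (ori == ter) stop_arch("ori and ter coincide after normalization")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length)
      stop_arch("sequence length (", nchar(sequence),
                ") does not match declared length (", length, ")")
    bad <- gsub("[ACGTN]", "", sequence)
    if (nchar(bad) > 0L)
      stop_arch("non-DNA characters in sequence of '", id, "': ",
                paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(list(id = as.character(id), length = length, ori = ori,
                 ter = ter, sequence = sequence),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("Circular genome '", x$id, "': ", x$length, " bp, ori = ", x$ori,
      ", ter = ", x$ter, if (is.null(x$sequence)) " (no sequence)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a circular genome from FASTA
#'
#' @param path path to a FASTA file.
#' @param ori,ter replication origin and terminus positions (0-based bp);
#'   normalized modulo the sequence length.
#' @param id record identifier to select when the file holds more than one
#'   record; required in that case.
#' @return a [circular_genome()].
#' @export
read_genome <- function(path, ori, ter, id = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop_arch("no sequence records in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (is.null(id)) {
    if (length(seqs) > 1L)
      stop_arch("file has ", length(seqs),
                " records; select one with `id` (available: ",
                paste(nm, collapse = ", "), ")")
    idx <- 1L
  } else {
    idx <- match(id, nm)
    if (is.na(idx)) stop_arch("record '", id, "' not found in ", path)
  }
  circular_genome(id = nm[idx], length = Biostrings::width(seqs)[idx],
                  ori = ori, ter = ter,
                  sequence = as.character(seqs[[idx]]))
}

#' Write a circular genome to FASTA
#'
#' @param genome a [circular_genome()] with a sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.null(genome$sequence)) stop_arch("genome has no sequence to write")
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

## ---- gene tables -----------------------------------------------------------

#' Construct a gene table
#'
#' One row per gene, in the internal coordinate convention (0-based,
#' half-open). Wrap-around genes have `start > end` and `wraps = TRUE`.
#' `flags` is a comma-separated set of class labels such as `"secreted"` or
#' `"clade_unique"`.
#'
#' @param gene_id,genome_id,start,end,strand,category,flags vectors of equal
#'   length (category and flags may be omitted).
#' @return a `data.frame` of class `gene_table`.
#' @export
gene_table <- function(gene_id, genome_id, start, end, strand,
                       category = "", flags = "") {
  n <- length(gene_id)
  strand <- as.character(strand)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop_arch("unknown strand symbol '", strand[bad[1]], "' for gene '",
              gene_id[bad[1]], "'")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end < 0L)) stop_arch("negative coordinates")
  df <- data.frame(gene_id = as.character(gene_id),
                   genome_id = rep_len(as.character(genome_id), n),
                   start = start, end = end, strand = strand,
                   category = rep_len(as.character(category), n),
                   flags = rep_len(as.character(flags), n),
                   wraps = start > end,
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_table", "data.frame")
  df
}

has_flag <- function(genes, flag) {
  vapply(strsplit(genes$flags, ","),
         function(f) flag %in% trimws(f), logical(1))
}

#' Read a gene coordinate table (GFF3 or TSV)
#'
#' External coordinates are 1-based inclusive and converted to the internal
#' 0-based half-open convention. A record whose external start exceeds its
#' end is taken to wrap the circular coordinate origin and flagged.
#'
#' In GFF3, the functional category is looked up in the `category=` attribute
#' and class flags in `flags=` (comma-separated). A TSV file must have a
#' header with at least `gene_id`, `genome_id`, `start`, `end`, `strand`;
#' `category` and `flags` are optional.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param genome_lengths optional named vector of genome lengths used to
#'   reject coordinates beyond the genome end.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, format = c("auto", "gff3", "tsv"),
                            genome_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    lines <- readLines(path)
    keep <- which(!grepl("^#", lines) & nzchar(lines))
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    nbad <- which(lengths(rows) < 8L)
    if (length(nbad))
      stop_arch("malformed GFF3 line ", keep[nbad[1]], " in ", path)
    get_attr <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
      vapply(m, function(x) if (length(x) == 2L) x[2] else "", character(1))
    }
    seqid <- vapply(rows, `[`, "", 1L)
    start1 <- as.integer(vapply(rows, `[`, "", 4L))
    end1 <- as.integer(vapply(rows, `[`, "", 5L))
    strand <- vapply(rows, `[`, "", 7L)
    attrs <- vapply(rows, function(x) if (length(x) >= 9L) x[9L] else "",
                    character(1))
    badstr <- which(!strand %in% c("+", "-"))
    if (length(badstr))
      stop_arch("unknown strand '", strand[badstr[1]], "' on line ",
                keep[badstr[1]], " of ", path)
    ids <- get_attr(attrs, "ID")
    ids[!nzchar(ids)] <- paste0("gene", seq_along(ids))[!nzchar(ids)]
    df <- gene_table(gene_id = ids, genome_id = seqid,
                     start = start1 - 1L, end = end1, strand = strand,
                     category = get_attr(attrs, "category"),
                     flags = get_attr(attrs, "flags"))
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("gene_id", "genome_id", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop_arch("TSV gene table missing column(s): ",
                paste(miss, collapse = ", "))
    badstr <- which(!tab$strand %in% c("+", "-"))
    if (length(badstr))
      stop_arch("unknown strand '", tab$strand[badstr[1]], "' on data row ",
                badstr[1], " of ", path)
    cat_col <- if ("category" %in% names(tab)) {
      x <- as.character(tab$category); x[is.na(x)] <- ""; x
    } else ""
    flag_col <- if ("flags" %in% names(tab)) {
      x <- as.character(tab$flags); x[is.na(x)] <- ""; x
    } else ""
    df <- gene_table(gene_id = tab$gene_id, genome_id = tab$genome_id,
                     start = tab$start - 1L, end = tab$end,
                     strand = tab$strand, category = cat_col,
                     flags = flag_col)
  }
  if (!is.null(genome_lengths)) {
    L <- genome_lengths[df$genome_id]
    over <- which(!is.na(L) & (df$start >= L | df$end > L))
    if (length(over))
      stop_arch("gene '", df$gene_id[over[1]],
                "' has coordinates beyond its genome length")
  }
  df
}

#' Write a gene table as TSV (1-based inclusive coordinates)
#'
#' @param genes a [gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, genome_id = genes$genome_id,
                    start = genes$start + 1L, end = genes$end,
                    strand = genes$strand, category = genes$category,
                    flags = genes$flags, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- ortholog matrices -----------------------------------------------------

#' Construct an ortholog copy-number matrix
#'
#' @param counts non-negative integer matrix, families in rows, taxa in
#'   columns; row and column names required and unique; every family must
#'   have at least one nonzero count.
#' @return integer matrix of class `ortholog_matrix`.
#' @export
ortholog_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_arch("ortholog matrix needs family row names and taxon column names")
  if (anyDuplicated(rownames(counts))) stop_arch("duplicate family ids")
  if (anyDuplicated(colnames(counts))) stop_arch("duplicate taxon ids")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_arch("counts must be non-negative integers")
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero))
    stop_arch("all-zero family rows: ", paste(head(zero, 5), collapse = ", "))
  storage.mode(counts) <- "integer"
  class(counts) <- c("ortholog_matrix", class(matrix()))
  counts
}

#' Read an ortholog copy-number matrix from TSV
#'
#' Header row holds the taxon ids, first column the family ids.
#'
#' @param path input path.
#' @return an [ortholog_matrix()].
#' @export
read_ortholog_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop_arch("non-numeric counts in ", path)
  ortholog_matrix(m)
}

#' @rdname read_ortholog_matrix
#' @param mat an [ortholog_matrix()].
#' @export
write_ortholog_matrix <- function(mat, path) {
  df <- data.frame(family = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- trees -----------------------------------------------------------------

## Parse internal-node labels into bootstrap supports on the percent scale.
## Labels in [0,1] are rescaled to [0,100] with a warning; non-numeric or
## empty labels become NA (missing, never 0).
.normalize_supports <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) {
    tree$support <- rep(NA_real_, n_int)
    return(tree)
  }
  sup <- suppressWarnings(as.numeric(lab))
  ok <- !is.na(sup)
  if (any(ok) && all(sup[ok] >= 0 & sup[ok] <= 1) && any(sup[ok] > 0)) {
    warning("support values look like proportions; rescaling to percent",
            call. = FALSE)
    sup[ok] <- sup[ok] * 100
  }
  if (any(ok & (sup < 0 | sup > 100)))
    stop_arch("support values outside [0,100]")
  tree$support <- sup
  tree
}

.check_tree <- function(tree, path = "<tree>") {
  if (anyDuplicated(tree$tip.label))
    stop_arch("duplicate leaf names in ", path, ": ",
              paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                    collapse = ", "))
  tree
}

#' Read rooted/unrooted trees from a Newick file
#'
#' Internal-node labels are parsed as bootstrap supports on the percent
#' scale; labels in \[0,1\] are rescaled to percent with a warning, and
#' unlabeled nodes get missing (NA) support. Each returned tree carries a
#' `support` vector aligned with its internal nodes.
#'
#' @param path path to a Newick file; multi-tree files are newline-delimited.
#' @param multi if `TRUE`, return all trees as a `multiPhylo` (a gene-tree
#'   set); if `FALSE`, the file must contain exactly one tree.
#' @return an [ape::read.tree()] `phylo`, or a `multiPhylo` when
#'   `multi = TRUE`.
#' @export
read_trees <- function(path, multi = FALSE) {
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop_arch("cannot parse Newick in ",
                                                  path, ": ",
                                                  conditionMessage(e)))
  if (is.null(trees)) stop_arch("no trees found in ", path)
  if (inherits(trees, "phylo")) trees <- c(trees) # -> multiPhylo, length 1
  trees <- lapply(trees, function(tr)
    .normalize_supports(.check_tree(tr, path)))
  if (multi) {
    class(trees) <- "multiPhylo"
    return(trees)
  }
  if (length(trees) != 1L)
    stop_arch(path, " contains ", length(trees),
              " trees; use multi = TRUE to read a tree set")
  trees[[1]]
}

#' Write trees to Newick, storing supports as internal node labels
#'
#' @param trees a `phylo` or `multiPhylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  out <- lapply(trees, function(tr) {
    if (!is.null(tr$support)) {
      lab <- ifelse(is.na(tr$support), "",
                    format(tr$support, trim = TRUE, scientific = FALSE))
      tr$node.label <- lab
    }
    tr$support <- NULL
    tr
  })
  class(out) <- "multiPhylo"
  ape::write.tree(out, file = path)
  invisible(path)
}

## ---- alignments ------------------------------------------------------------

#' Read a multiple sequence alignment from FASTA
#'
#' @param path input path.
#' @return an upper-case character matrix (sequences in rows, sites in
#'   columns) with sequence ids as row names; all rows must be equally long
#'   and there must be at least two.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2L) stop_arch("alignment needs at least 2 sequences")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop_arch("aligned rows have unequal lengths in ", path)
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- sub("\\s.*$", "", names(seqs))
  m
}

#' @rdname read_alignment
#' @param aln character matrix alignment.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a growth curve (CSV with columns time_min, od)
#'
#' @param path input path.
#' @return data.frame with numeric `time_min` and `od`.
#' @export
read_growth_curve <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("time_min", "od") %in% names(df)))
    stop_arch("growth curve CSV needs columns time_min, od")
  df[c("time_min", "od")]
}
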