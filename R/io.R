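# Readers/writers for the standard formats the pipeline touches:
# MatrixMarket expression directories, AIRR rearrangement TSV, FASTA germline
# segments, gene-set lists and CSV score tables.

#' Sparse expression matrix container
#'
#' A light S3 container holding a sparse count matrix (genes as rows, cell
#' barcodes as columns, the 10x convention) together with a layer tag telling
#' whether values are raw integer counts or log-normalized expression.
#'
#' @param counts A matrix or `Matrix::dgCMatrix` with unique row (gene) and
#'   column (barcode) names.
#' @param layer `"raw"` (nonnegative integers) or `"lognorm"` (nonnegative reals).
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(counts, layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  genes <- rownames(counts)
  cells <- colnames(counts)
  if (is.null(genes) || is.null(cells)) abort("counts must have gene and barcode dimnames")
  if (anyDuplicated(genes)) abort("duplicate gene symbols")
  if (anyDuplicated(cells)) abort("duplicate cell barcodes")
  if (any(counts@x < 0)) abort("negative entries are not allowed")
  if (layer == "raw" && any(counts@x != round(counts@x))) {
    abort("raw layer must hold integer counts")
  }
  structure(list(counts = counts, layer = layer), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d cells (%s layer, %d nonzeros)\n",
    nrow(x$counts), ncol(x$counts), x$layer, length(x$counts@x)
  ))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname expr_matrix
#' @export
n_genes <- function(x) nrow(x$counts)

#' Read / write a 10x-style MatrixMarket directory
#'
#' The directory holds `matrix.mtx` (coordinate format), `genes.tsv` (or
#' `features.tsv`) and `barcodes.tsv`. Dimensions are checked against the
#' matrix header; integer counts round-trip bit-exactly.
#'
#' @param path Directory path.
#' @return `read_mtx_dir()` returns an [expr_matrix()] with genes and cells in
#'   file order.
#' @export
read_mtx_dir <- function(path) {
  mtx_file <- file.path(path, "matrix.mtx")
  gene_file <- file.path(path, "genes.tsv")
  if (!file.exists(gene_file)) gene_file <- file.path(path, "features.tsv")
  bc_file <- file.path(path, "barcodes.tsv")
  for (f in c(mtx_file, gene_file, bc_file)) {
    if (!file.exists(f)) abort(paste("missing file:", f))
  }
  m <- Matrix::readMM(mtx_file)
  genes <- readLines(gene_file)
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1)
  cells <- readLines(bc_file)
  if (nrow(m) != length(genes)) {
    abort(sprintf("matrix header says %d genes but gene list has %d", nrow(m), length(genes)))
  }
  if (ncol(m) != length(cells)) {
    abort(sprintf("matrix header says %d cells but barcode list has %d", ncol(m), length(cells)))
  }
  dimnames(m) <- list(genes, cells)
  expr_matrix(m, layer = "raw")
}

#' @rdname read_mtx_dir
#' @param x An [expr_matrix()] with raw counts.
#' @export
write_mtx_dir <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(path, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

# map a c_call (constant-region gene name) to an isotype label by prefix
parse_isotype <- function(c_call) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", as.character(c_call)))
  key <- sub("^IGH", "IG", key)
  prefixes <- c(
    IGM = "IgM", IGD = "IgD", IGG1 = "IgG1", IGG2B = "IgG2b", IGG2C = "IgG2c",
    IGG3 = "IgG3", IGA = "IgA", IGE = "IgE"
  )
  out <- rep("unknown", length(key))
  # longest prefixes first so IGG2B is not swallowed by a shorter match
  for (p in names(prefixes)[order(nchar(names(prefixes)), decreasing = TRUE)]) {
    hit <- out == "unknown" & startsWith(key, p)
    out[hit] <- prefixes[[p]]
  }
  out
}

#' Read an AIRR rearrangement TSV
#'
#' Accepts standard AIRR column names. `cdr3_aa` may be absent if `junction_aa`
#' is present, in which case the CDR3 is derived by trimming the conserved
#' flanking residues (first and last amino acid of the junction). Rows lacking
#' a CDR3 or V call are returned separately with reasons rather than dropped.
#'
#' @param path TSV file path.
#' @return List with `rearrangements` (tibble, one row per usable record, with
#'   a parsed `isotype` column) and `rejected` (tibble of row number + reason).
#' @export
read_airr <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("cell_id", "v_call", "j_call", "c_call")
  missing_cols <- setdiff(mandatory, names(df))
  if (!("cdr3_aa" %in% names(df)) && !("junction_aa" %in% names(df))) {
    missing_cols <- c(missing_cols, "cdr3_aa (or junction_aa)")
  }
  if (length(missing_cols) > 0) {
    abort(paste("AIRR file is missing mandatory columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!("cdr3_aa" %in% names(df))) {
    df$cdr3_aa <- ifelse(
      is.na(df$junction_aa) | nchar(df$junction_aa) < 3, NA_character_,
      substr(df$junction_aa, 2, nchar(df$junction_aa) - 1)
    )
  }
  df$.row <- seq_len(nrow(df))
  bad_cdr3 <- is.na(df$cdr3_aa) | df$cdr3_aa == ""
  bad_v <- is.na(df$v_call) | df$v_call == ""
  rejected <- dplyr::bind_rows(
    tibble(row = df$.row[bad_cdr3], reason = "missing CDR3"),
    tibble(row = df$.row[bad_v & !bad_cdr3], reason = "missing v_call")
  ) |> dplyr::arrange(.data$row)
  keep <- df[!(bad_cdr3 | bad_v), , drop = FALSE]
  keep$.row <- NULL
  keep$isotype <- parse_isotype(keep$c_call)
  if ("sequence_alignment" %in% names(keep) && "germline_alignment" %in% names(keep)) {
    mism <- nchar(keep$sequence_alignment) != nchar(keep$germline_alignment)
    if (any(mism, na.rm = TRUE)) {
      abort("sequence_alignment and germline_alignment lengths differ in some rows")
    }
  }
  list(rearrangements = as_tibble(keep), rejected = rejected)
}

#' @rdname read_airr
#' @param rearrangements Tibble of rearrangement records.
#' @export
write_airr <- function(rearrangements, path) {
  readr::write_tsv(rearrangements, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-set file
#'
#' One gene symbol per line; `#` starts a comment; duplicates are dropped with
#' a warning, order is preserved, matching is case-sensitive after whitespace
#' strip.
#'
#' @param path File path.
#' @param name Set name (defaults to the file stem).
#' @return A `gene_set` object: list with `name` and `genes`.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- lines[lines != ""]
  if (length(genes) == 0) abort(paste("gene-set file is empty:", path))
  if (anyDuplicated(genes)) {
    warn(sprintf("%d duplicate gene(s) dropped from %s", sum(duplicated(genes)), path))
    genes <- genes[!duplicated(genes)]
  }
  gene_set(name %||% sub("\\.[^.]*$", "", basename(path)), genes)
}

#' @rdname read_gene_set
#' @param genes Character vector of unique gene symbols.
#' @export
gene_set <- function(name, genes) {
  genes <- trimws(as.character(genes))
  if (length(genes) == 0) abort("gene set must be nonempty")
  if (anyDuplicated(genes)) abort("gene set genes must be unique")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @rdname read_gene_set
#' @param x A `gene_set`.
#' @export
write_gene_set <- function(x, path) {
  writeLines(x$genes, path)
  invisible(path)
}

#' Write a per-cell score table to CSV
#'
#' @param scores Tibble with one row per cell (see [score_cells()]).
#' @param path Output CSV path.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' Read germline V/J segments from FASTA
#'
#' Headers may carry `cdr1_start=<i> cdr1_end=<j>` annotations giving the CDR1
#' window in 1-based alignment coordinates; these propagate to simulated
#' rearrangements and drive the W33L analysis.
#'
#' @param path FASTA file of amino-acid segments.
#' @return Tibble with `segment`, `seq`, `cdr1_start`, `cdr1_end`.
#' @export
read_germline_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("missing germline file:", path))
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  grab <- function(field) {
    m <- regmatches(headers, regexpr(paste0(field, "=[0-9]+"), headers))
    out <- rep(NA_integer_, length(headers))
    hit <- grepl(paste0(field, "=[0-9]+"), headers)
    out[hit] <- as.integer(sub(paste0(field, "="), "", m))
    out
  }
  tibble(
    segment = vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1),
    seq = unname(as.character(seqs)),
    cdr1_start = grab("cdr1_start"),
    cdr1_end = grab("cdr1_end")
  )
}

#' Packaged synthetic germline segments
#'
#' Paths to the small synthetic germline V and J amino-acid segment sets
#' bundled with the package (10 V, 4 J). These are invented analogs for
#' simulation and testing, not curated germline databases; the `VH1-72` analog
#' carries tryptophan at aligned position 33 (CDR1 window position 8).
#'
#' @param which `"v"` or `"j"`.
#' @return File path.
#' @export
germline_fasta_path <- function(which = c("v", "j")) {
  which <- match.arg(which)
  system.file("extdata", paste0("germline_", which, "_synthetic.fasta"),
              package = "clonesurveil", mustWork = TRUE)
}
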