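#' @importFrom stats cor cov dist hclust p.adjust pbeta prcomp pt rbinom
#'   rlnorm rnbinom rnorm rpois runif sd var as.dist setNames
#' @importFrom utils read.delim write.table head
NULL

# shortest decimal representation that parses back to the identical double,
# so every writer/reader pair round-trips bit-exactly
.fmt_dbl <- function(x) {
  s <- sprintf("%.15g", x)
  for (d in c("%.16g", "%.17g")) {
    bad <- is.finite(x) & as.numeric(s) != x
    if (!any(bad)) break
    s[bad] <- sprintf(d, x[bad])
  }
  s[is.na(x)] <- NA
  s
}

# apply .fmt_dbl to every double column before write.table
.fmt_frame <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]) && !all(df[[j]] == round(df[[j]]), na.rm = TRUE))
      df[[j]] <- .fmt_dbl(df[[j]])
  }
  df
}

# ---------------------------------------------------------------------------
# Spectral-count table
# ---------------------------------------------------------------------------

#' Construct a spectral-count table
#'
#' The raw quantitative substrate of the pipeline: an integer matrix of
#' MS/MS spectra assigned to each protein (rows) in each sample (columns),
#' together with per-sample group labels and (optionally) a parallel matrix
#' of unique-peptide counts backing the inclusion filter.
#'
#' @param counts integer matrix, proteins x samples, with unique rownames
#'   (protein accessions) and colnames (sample ids). All values must be
#'   non-negative integers.
#' @param groups named character vector mapping every sample id to a group
#'   label (e.g. `"control"`, `"injured"`).
#' @param unique_peptides optional integer matrix of the same shape giving
#'   the number of unique peptides observed per protein and sample. When
#'   `NULL`, defaults to the support of `counts` (1 where a spectrum was
#'   assigned, 0 elsewhere).
#' @return an object of class `spectral_count_table`: a list with elements
#'   `counts`, `unique_peptides`, `groups`.
#' @export
spectral_count_table <- function(counts, groups, unique_peptides = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate protein accession: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at protein '%s', sample '%s': must be a non-negative integer",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  missing_grp <- setdiff(colnames(counts), names(groups))
  if (length(missing_grp) > 0)
    stop("sample(s) without group label: ", paste(missing_grp, collapse = ", "))
  groups <- groups[colnames(counts)]
  if (is.null(unique_peptides)) {
    unique_peptides <- (counts > 0) * 1
    dimnames(unique_peptides) <- dimnames(counts)
  } else {
    unique_peptides <- as.matrix(unique_peptides)
    storage.mode(unique_peptides) <- "double"
    if (!identical(dim(unique_peptides), dim(counts)))
      stop("unique_peptides must have the same shape as counts")
    dimnames(unique_peptides) <- dimnames(counts)
    if (any(is.na(unique_peptides) | unique_peptides < 0 |
            unique_peptides != round(unique_peptides)))
      stop("unique_peptides must be non-negative integers")
  }
  structure(list(counts = counts, unique_peptides = unique_peptides,
                 groups = groups),
            class = "spectral_count_table")
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf("spectral_count_table: %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s=%s", names(x$groups), x$groups),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Read a spectral-count TSV
#'
#' Expects a UTF-8 TSV whose first column is the protein accession
#' (header `accession`) and whose remaining columns are sample counts,
#' optionally accompanied by parallel `<sample>.unique_peptides` columns.
#' Missing cells are read as zero (an unidentified protein has no assigned
#' spectra) with a warning reporting how many were filled.
#'
#' @param path file path.
#' @param group_map named character vector sample id -> group label; every
#'   sample column in the file must be present.
#' @return a [spectral_count_table()].
#' @export
read_count_table <- function(path, group_map) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an accession column plus samples")
  acc <- as.character(df[[1]])
  if (anyDuplicated(acc))
    stop("duplicate protein accession: ", acc[duplicated(acc)][1L])
  cols <- colnames(df)[-1]
  up_cols <- grep("\\.unique_peptides$", cols, value = TRUE)
  smp_cols <- setdiff(cols, up_cols)
  unknown <- setdiff(smp_cols, names(group_map))
  if (length(unknown) > 0)
    stop("sample(s) in file absent from group_map: ",
         paste(unknown, collapse = ", "))
  cnt <- as.matrix(df[smp_cols])
  rownames(cnt) <- acc
  n_missing <- sum(is.na(cnt))
  if (n_missing > 0) {
    warning(sprintf("%d missing cell(s) read as 0", n_missing))
    cnt[is.na(cnt)] <- 0
  }
  up <- NULL
  if (length(up_cols) > 0) {
    want <- paste0(smp_cols, ".unique_peptides")
    if (!all(want %in% up_cols))
      stop("unique_peptides columns incomplete; need one per sample")
    up <- as.matrix(df[want])
    up[is.na(up)] <- 0
    colnames(up) <- smp_cols
    rownames(up) <- acc
  }
  spectral_count_table(cnt, group_map, unique_peptides = up)
}

#' Write a spectral-count table as TSV
#'
#' Emits the same dialect [read_count_table()] consumes, so a write/read
#' round trip reproduces the table exactly.
#'
#' @param x a `spectral_count_table`.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(accession = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  up <- x$unique_peptides
  colnames(up) <- paste0(colnames(x$counts), ".unique_peptides")
  df <- cbind(df, up)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Protein metadata and molecular mass
# ---------------------------------------------------------------------------

# Average (isotope-abundance-weighted) residue masses in daltons, standard
# 20-letter code; X is resolved to the unweighted mean residue mass on request.
.residue_mass <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
.water_mass <- 18.0153

#' Average molecular mass of a protein sequence, in kDa
#'
#' Sums standard average residue masses over the sequence and adds one
#' water (18.0153 Da). This is the denominator of the spectra-per-kDa
#' abundance index when no curated mass is supplied.
#'
#' @param sequence amino-acid string over the 20 standard letters.
#' @param allow_x if `TRUE`, the letter `X` is tolerated and contributes the
#'   mean standard residue mass; otherwise any non-standard letter is an
#'   error naming its position.
#' @return mass in kilodaltons.
#' @export
mass_from_sequence <- function(sequence, allow_x = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  m <- .residue_mass[aa]
  if (anyNA(m)) {
    pos <- which(is.na(m))
    if (allow_x && all(aa[pos] == "X")) {
      m[pos] <- mean(.residue_mass)
    } else {
      bad <- pos[aa[pos] != "X" | !allow_x][1L]
      stop(sprintf("non-standard amino-acid letter '%s' at position %d",
                   aa[bad], bad))
    }
  }
  (sum(m) + .water_mass) / 1000
}

#' Read protein metadata
#'
#' TSV with columns `accession`, `gene_symbol`, `description`, `mass_kda`,
#' `ecm_category`. Gene symbols are uppercased at ingest so matching across
#' tables is case-insensitive. `ecm_category` must be one of collagen,
#' proteoglycan, glycoprotein, laminin, other.
#'
#' @param path file path.
#' @return data.frame of class `protein_meta`.
#' @export
read_protein_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "gene_symbol", "description", "mass_kda", "ecm_category")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) stop("protein meta missing column(s): ",
                             paste(miss, collapse = ", "))
  protein_meta(df)
}

#' Construct/validate protein metadata
#' @param df data.frame with columns accession, gene_symbol, description,
#'   mass_kda, ecm_category.
#' @return the validated data.frame, gene symbols uppercased.
#' @export
protein_meta <- function(df) {
  if (anyDuplicated(df$accession))
    stop("duplicate accession in protein meta: ",
         df$accession[duplicated(df$accession)][1L])
  df$gene_symbol <- toupper(df$gene_symbol)
  ok_cat <- c("collagen", "proteoglycan", "glycoprotein", "laminin", "other")
  if (!all(is.na(df$ecm_category) | df$ecm_category %in% ok_cat))
    stop("ecm_category must be one of: ", paste(ok_cat, collapse = ", "))
  bad <- which(!is.na(df$mass_kda) & df$mass_kda <= 0)
  if (length(bad) > 0)
    stop("non-positive mass_kda for accession ", df$accession[bad[1]])
  class(df) <- c("protein_meta", "data.frame")
  df
}

#' Write protein metadata TSV
#' @param meta protein_meta data.frame.
#' @param path output path.
#' @export
write_protein_meta <- function(meta, path) {
  cols <- c("accession", "gene_symbol", "description", "mass_kda", "ecm_category")
  write.table(.fmt_frame(as.data.frame(meta)[cols]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive protein masses from a FASTA file
#'
#' Reads a standard amino-acid FASTA (via Biostrings when available, else a
#' minimal internal reader) and returns a named vector of masses in kDa
#' computed by [mass_from_sequence()]. FASTA record ids are taken up to the
#' first whitespace.
#'
#' @param path FASTA path.
#' @param allow_x passed to [mass_from_sequence()].
#' @return named numeric vector, kDa per accession.
#' @export
mass_from_fasta <- function(path, allow_x = TRUE) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readAAStringSet(path)
    nm <- sub("\\s.*$", "", names(seqs))
    setNames(vapply(as.character(seqs), mass_from_sequence,
                    numeric(1), allow_x = allow_x, USE.NAMES = FALSE), nm)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0,
                   character(1), collapse = "")
    setNames(vapply(seqs, mass_from_sequence, numeric(1),
                    allow_x = allow_x, USE.NAMES = FALSE), id)
  }
}

# ---------------------------------------------------------------------------
# Edge, annotation, transcript and alias tables
# ---------------------------------------------------------------------------

#' Read a protein-association edge table
#'
#' Three-column TSV (`node_a`, `node_b`, `score`). Scores are accepted on
#' either the raw String 0-1000 scale or on 0-1, auto-detected by whether
#' the maximum exceeds 1, and normalized to 0-1. Self-edges are dropped
#' with a warning; node symbols are uppercased.
#'
#' @param path file path.
#' @return data.frame of class `edge_table` with columns node_a, node_b,
#'   score.
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge table needs columns node_a, node_b, score")
  colnames(df)[1:3] <- c("node_a", "node_b", "score")
  edge_table(df[1:3])
}

#' Construct/validate an edge table
#' @param df data.frame with columns node_a, node_b, score.
#' @return validated `edge_table` (scores on 0-1, self-edges removed,
#'   symbols uppercased).
#' @export
edge_table <- function(df) {
  df$node_a <- toupper(df$node_a)
  df$node_b <- toupper(df$node_b)
  df$score <- as.numeric(df$score)
  if (any(is.na(df$score))) stop("non-numeric association score")
  if (any(df$score < 0)) stop("negative association score at row ",
                              which(df$score < 0)[1])
  if (max(df$score, 0) > 1) {
    if (max(df$score) > 1000)
      stop("association score above 1000 at row ", which.max(df$score))
    df$score <- df$score / 1000
  }
  self <- df$node_a == df$node_b
  if (any(self)) {
    warning(sprintf("dropped %d self-edge(s)", sum(self)))
    df <- df[!self, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("edge_table", "data.frame")
  df
}

#' Write an edge table TSV
#' @param edges edge_table.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  write.table(.fmt_frame(as.data.frame(edges)[c("node_a", "node_b", "score")]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set annotation table (TSV or GMT)
#'
#' TSV dialect: four columns `term_id`, `term_name`, `namespace`
#' (BP/MF/CC), `gene_symbol`, one row per (term, gene) pair. GMT dialect
#' (detected by a `.gmt` extension or by `format = "gmt"`): one term per
#' line, `term_id<TAB>description<TAB>gene...`; the namespace defaults to
#' BP. Duplicated (term, gene) pairs collapse to one record with a warning.
#'
#' @param path file path.
#' @param format `"auto"`, `"tsv"` or `"gmt"`.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", l)
      data.frame(term_id = f[1], term_name = f[2], namespace = "BP",
                 gene_symbol = f[-(1:2)], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("term_id", "term_name", "namespace", "gene_symbol")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0) stop("annotation table missing column(s): ",
                               paste(miss, collapse = ", "))
  }
  annotation_table(df)
}

#' Construct/validate an annotation table
#' @param df data.frame with columns term_id, term_name, namespace,
#'   gene_symbol.
#' @return validated `annotation_table`, symbols uppercased, duplicates
#'   collapsed.
#' @export
annotation_table <- function(df) {
  if (!all(df$namespace %in% c("BP", "MF", "CC")))
    stop("unknown namespace: ",
         df$namespace[!df$namespace %in% c("BP", "MF", "CC")][1])
  df$gene_symbol <- toupper(df$gene_symbol)
  dup <- duplicated(df[c("term_id", "gene_symbol")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated (term, gene) pair(s)", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write an annotation table TSV
#' @param ann annotation_table.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  cols <- c("term_id", "term_name", "namespace", "gene_symbol")
  write.table(as.data.frame(ann)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a transcript differential-expression table
#'
#' Four-column TSV: `gene_symbol`, `fold_change` (positive, case/control),
#' `p_value`, `direction` (up/down). Direction must be consistent with the
#' fold change relative to 1 when both are present.
#'
#' @param path file path.
#' @return data.frame of class `transcript_de_table`.
#' @export
read_transcript_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "fold_change", "p_value", "direction")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) stop("transcript table missing column(s): ",
                             paste(miss, collapse = ", "))
  transcript_de_table(df)
}

#' Construct/validate a transcript DE table
#' @param df data.frame with columns gene_symbol, fold_change, p_value,
#'   direction.
#' @return validated `transcript_de_table`, symbols uppercased.
#' @export
transcript_de_table <- function(df) {
  df$gene_symbol <- toupper(df$gene_symbol)
  if (any(df$fold_change <= 0, na.rm = TRUE))
    stop("fold_change must be positive")
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE))
    stop("p_value outside [0,1]")
  if (!all(df$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  bad <- (df$direction == "up" & df$fold_change < 1) |
         (df$direction == "down" & df$fold_change > 1)
  if (any(bad, na.rm = TRUE))
    stop("direction inconsistent with fold_change for gene ",
         df$gene_symbol[which(bad)[1]])
  rownames(df) <- NULL
  class(df) <- c("transcript_de_table", "data.frame")
  df
}

#' Write a transcript DE table TSV
#' @param tr transcript_de_table.
#' @param path output path.
#' @export
write_transcript_table <- function(tr, path) {
  cols <- c("gene_symbol", "fold_change", "p_value", "direction")
  write.table(.fmt_frame(as.data.frame(tr)[cols]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a symbol alias map
#'
#' Two-column TSV `symbol<TAB>canonical`, applied before any cross-table
#' symbol matching. Both columns are uppercased.
#'
#' @param path file path.
#' @return named character vector alias -> canonical.
#' @export
read_alias_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("alias map needs two columns: symbol, canonical")
  setNames(toupper(df[[2]]), toupper(df[[1]]))
}

#' Canonicalize gene symbols
#'
#' Uppercases and applies an optional alias map; symbols without an alias
#' entry pass through unchanged.
#'
#' @param symbols character vector.
#' @param alias optional named vector from [read_alias_map()].
#' @return character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(symbols, alias = NULL) {
  s <- toupper(symbols)
  if (!is.null(alias)) {
    hit <- s %in% names(alias)
    s[hit] <- unname(alias[s[hit]])
  }
  s
}
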