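# Readers and writers for the external formats the screen touches.
#
# Coordinate contract: everything inside the package is 0-based half-open on
# the + strand of the stored sequence (BED convention). GFF3, the only
# 1-based input, is converted on read.

ANNOTATION_KINDS <- c("gene", "exon", "repeat", "cre_truth")

#' Construct a genome locus
#'
#' A named sequence interval with species, strand and id. Sequences are
#' uppercase over `A,C,G,T,N`; other IUPAC ambiguity codes are converted to
#' `N`, anything else is an error.
#'
#' @param species,chrom,id labels.
#' @param seq DNA string.
#' @param start,end 0-based half-open interval; default spans `seq`.
#' @param strand `"+"` or `"-"`.
#' @return object of class `genome_locus`.
#' @export
genome_locus <- function(seq, id = "locus", species = "unknown",
                         chrom = id, start = 0L, end = start + nchar(seq),
                         strand = "+") {
  seq <- toupper(seq)
  seq <- chartr("URYSWKMBDHV", "NNNNNNNNNNN", seq)
  bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
  if (length(bad) && nchar(bad))
    stop(sprintf("invalid character '%s' in sequence record '%s'", bad, id))
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("end must be > start")
  if (nchar(seq) != end - start) stop("sequence length must equal end - start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(species = species, chrom = chrom, start = start, end = end,
                 strand = strand, seq = seq, id = id),
            class = "genome_locus")
}

#' @export
print.genome_locus <- function(x, ...) {
  cat(sprintf("genome_locus %s (%s) %s:[%d,%d)%s, %d bp\n", x$id, x$species,
              x$chrom, x$start, x$end, x$strand, nchar(x$seq)))
  invisible(x)
}

#' Read a FASTA file into genome loci
#'
#' Parsed with [Biostrings::readBStringSet()]; the id of each locus is the
#' first whitespace-delimited header token. Lowercase is uppercased;
#' non-IUPAC characters raise an error naming the character and the record.
#'
#' @param path FASTA file.
#' @param species species label attached to every locus.
#' @return named list of `genome_locus`, in file order.
#' @export
read_fasta <- function(path, species = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  loci <- lapply(seq_along(set), function(i)
    genome_locus(as.character(set[[i]]), id = ids[i], species = species,
                 chrom = ids[i]))
  setNames(loci, ids)
}

#' Write genome loci as FASTA
#'
#' @param loci list of `genome_locus`.
#' @param path output file.
#' @export
write_fasta <- function(loci, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (l in loci) {
    writeLines(paste0(">", l$id), con)
    writeLines(gsub("(.{70})", "\\1\n", l$seq, perl = TRUE), con)
  }
  invisible(path)
}

#' Construct an annotation set
#'
#' @param chrom,start,end,strand,kind,name parallel vectors; intervals are
#'   0-based half-open, kinds restricted to
#'   `gene`, `exon`, `repeat`, `cre_truth`.
#' @return data.frame of class `annotation_set`.
#' @export
annotation_set <- function(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           kind = character(), name = character()) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   kind = as.character(kind), name = as.character(name),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("annotation intervals must have start < end")
  bad <- setdiff(unique(df$kind), ANNOTATION_KINDS)
  if (length(bad)) stop("unknown annotation kind(s): ", paste(bad, collapse = ", "))
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Read 6-column BED annotations
#'
#' Coordinates are kept 0-based half-open; column 4 is parsed as
#' `"kind:name"`.
#'
#' @param path BED6 file.
#' @return an [annotation_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(annotation_set())
  tab <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("expected 6-column BED: ", path)
  bad <- which(tab[[3L]] <= tab[[2L]])
  if (length(bad))
    stop(sprintf("start >= end at line %d of %s", bad[1L], path))
  kn <- strsplit(tab[[4L]], ":", fixed = TRUE)
  kind <- vapply(kn, `[[`, character(1), 1L)
  name <- vapply(kn, function(x) paste(x[-1L], collapse = ":"), character(1))
  annotation_set(tab[[1L]], tab[[2L]], tab[[3L]], tab[[6L]], kind, name)
}

#' Write an annotation set as BED6
#'
#' Inverse of [read_bed()]: column 4 is `"kind:name"`, column 5 is 0.
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @export
write_bed <- function(ann, path) {
  df <- data.frame(ann$chrom, ann$start, ann$end,
                   paste0(ann$kind, ":", ann$name), 0L, ann$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GFF3 annotations
#'
#' 1-based inclusive GFF3 coordinates are converted to the package's
#' 0-based half-open convention. Feature types `gene` and `exon` are kept
#' as-is; `repeat_region` and `low_complexity_region` map to kind
#' `repeat`; other types are dropped. Names come from the `Name=` or `ID=`
#' attribute.
#'
#' @param path GFF3 file.
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) != 9L) stop("expected 9-column GFF3: ", path)
  map <- c(gene = "gene", exon = "exon", repeat_region = "repeat",
           low_complexity_region = "repeat")
  keep <- tab[[3L]] %in% names(map)
  tab <- tab[keep, , drop = FALSE]
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0(key, "="), a))) > 0 &
             nchar(m) > 0, sub(paste0(key, "="), "", m), NA_character_)
  }
  nm <- vapply(tab[[9L]], function(a) {
    v <- regmatches(a, regexpr("Name=[^;]+", a))
    if (!length(v)) v <- regmatches(a, regexpr("ID=[^;]+", a))
    if (!length(v)) return("unnamed")
    sub("^(Name|ID)=", "", v)
  }, character(1), USE.NAMES = FALSE)
  annotation_set(tab[[1L]], tab[[4L]] - 1L, tab[[5L]], tab[[7L]],
                 unname(map[tab[[3L]]]), nm)
}

#' Read a homolog-gene table
#'
#' Two tab-separated columns: a species-A gene id and a comma-separated
#' list of species-B gene ids (one-to-many homology allowed). Returns one
#' row per (gene_a, gene_b) combination.
#'
#' @param path TSV file.
#' @return data.frame of class `homology_table` with columns
#'   `gene_a`, `gene_b`.
#' @export
read_homology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("homology table rows need 2 tab-separated columns")
    data.frame(gene_a = f[1L],
               gene_b = trimws(strsplit(f[2L], ",", fixed = TRUE)[[1L]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows) %||% data.frame(gene_a = character(),
                                             gene_b = character())
  class(df) <- c("homology_table", "data.frame")
  df
}

#' Write a homology table
#'
#' @param homology a `homology_table` (or data.frame with `gene_a`,
#'   `gene_b`).
#' @param path output TSV.
#' @export
write_homology <- function(homology, path) {
  sp <- split(homology$gene_b, homology$gene_a)
  writeLines(vapply(names(sp), function(g)
    paste0(g, "\t", paste(sp[[g]], collapse = ",")), character(1)), path)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2016+ text dialect: a `">ID name"` header followed by
#' four rows like `"A [ 4 0 12 ]"`. Rows may appear in any order and are
#' returned in A,C,G,T order. Counts must be non-negative and all four base
#' rows present.
#'
#' @param path PFM text file (may contain several records).
#' @return named list of 4 x width count matrices (rownames A,C,G,T), with
#'   attributes `id` and `name`.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records (no '>' header) in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (r in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[r]]), "\\s+")[[1L]]
    id <- hdr[1L]; nm <- if (length(hdr) > 1L) hdr[2L] else hdr[1L]
    body <- lines[(starts[r] + 1L):ends[r]]
    rows <- list()
    for (b in body) {
      m <- regmatches(b, regexec("^\\s*([ACGT])\\s*\\[?([-0-9. \\t]+)\\]?\\s*$", b))[[1L]]
      if (length(m) == 0L) stop("unparseable PFM row in record ", id, ": ", b)
      counts <- as.numeric(strsplit(trimws(m[3L]), "\\s+")[[1L]])
      rows[[m[2L]]] <- counts
    }
    missing <- setdiff(DNA_BASES, names(rows))
    if (length(missing))
      stop("record ", id, " is missing base row(s): ",
           paste(missing, collapse = ", "))
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("record ", id, ": rows have unequal widths")
    if (w < 1L) stop("record ", id, ": matrix must have at least one column")
    mat <- do.call(rbind, rows[DNA_BASES])
    if (any(mat < 0)) stop("record ", id, ": negative count")
    attr(mat, "id") <- id; attr(mat, "name") <- nm
    out[[id]] <- mat
  }
  out
}

#' Write classified screen candidates
#'
#' Writes a BED6 file of the species-A intervals (column 4 is
#' `cre_truth:<id>` so the file re-reads as an [annotation_set()], score
#' column 0) and a TSV report with one row per candidate: identity,
#' aligned length, E-value, the four criterion booleans, the
#' reciprocal-uniqueness flag, refined identity, binding-site hit count and
#' verdict. Headers are written even when there are no candidates.
#'
#' @param candidates list of classified `candidate_cre` objects.
#' @param path_bed,path_tsv output paths.
#' @export
write_candidates <- function(candidates, path_bed, path_tsv) {
  for (cc in candidates)
    if (any(is.na(unlist(cc$criteria))))
      stop("unclassified candidate: ", cc$id, " (run apply_criteria first)")
  tsv <- candidates_report(candidates)
  write.table(tsv, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_lines <- vapply(candidates, function(cc)
    paste(cc$query$chrom, cc$query$start, cc$query$end,
          paste0("cre_truth:", cc$id), 0L, "+", sep = "\t"), character(1))
  writeLines(bed_lines, path_bed)
  invisible(path_tsv)
}

#' Tabular report over candidates
#'
#' @param candidates list of `candidate_cre` objects.
#' @return data.frame, one row per candidate.
#' @export
candidates_report <- function(candidates) {
  cols <- data.frame(
    id = character(), query_chrom = character(), query_start = integer(),
    query_end = integer(), hit_chrom = character(), hit_start = integer(),
    hit_end = integer(), hit_strand = character(), gene_a = character(),
    gene_b = character(), score = integer(), identity = numeric(),
    n_columns = integer(), evalue = numeric(), homolog_linked = logical(),
    identity_length_evalue = logical(), noncoding = logical(),
    nonrepetitive = logical(), reciprocal_unique = character(),
    refined_identity = numeric(), tfbs_hits = integer(), verdict = character(),
    stringsAsFactors = FALSE)
  if (!length(candidates)) return(cols)
  do.call(rbind, lapply(candidates, function(cc) data.frame(
    id = cc$id, query_chrom = cc$query$chrom, query_start = cc$query$start,
    query_end = cc$query$end, hit_chrom = cc$hit$chrom,
    hit_start = cc$hit$start, hit_end = cc$hit$end,
    hit_strand = cc$hit$strand, gene_a = cc$linked_gene_pair[1L],
    gene_b = cc$linked_gene_pair[2L], score = cc$alignment$score,
    identity = cc$alignment$identity, n_columns = cc$alignment$n_columns,
    evalue = cc$alignment$evalue,
    homolog_linked = cc$criteria$homolog_linked,
    identity_length_evalue = cc$criteria$identity_length_evalue,
    noncoding = cc$criteria$noncoding,
    nonrepetitive = cc$criteria$nonrepetitive,
    reciprocal_unique = as.character(cc$reciprocal_unique),
    refined_identity = ifelse(is.null(cc$refined_identity), NA_real_,
                              cc$refined_identity),
    tfbs_hits = cc$tfbs_hits %||% NA_integer_,
    verdict = cc$verdict, stringsAsFactors = FALSE)))
}
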