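# Readers and writers for FASTA / VCF / BED / TSV, YAML run configuration,
# and the end-to-end pipeline driver.

#' Read a FASTA file of named sequences
#'
#' Sequences are uppercased and U is read as T. Record names are the first
#' whitespace-delimited token of each header; duplicate or empty names are
#' rejected. Order is preserved.
#'
#' @param path FASTA file path.
#' @return A named character vector of A/C/G/T/N sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("FASTA record with empty ID in ", path)
  if (anyDuplicated(nm))
    stop("duplicate FASTA IDs in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- vapply(as.character(set), norm_seq, character(1), USE.NAMES = FALSE)
  bad <- !grepl("^[ACGTN]*$", seqs)
  if (any(bad))
    stop("non-nucleotide characters in FASTA record(s): ",
         paste(nm[bad], collapse = ", "))
  stats::setNames(seqs, nm)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector (or `DNAStringSet`).
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs); seqs <- stats::setNames(as.character(seqs), nm)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read variant candidates from a VCF file
#'
#' Uses VariantAnnotation; multi-allelic records are split into one
#' candidate per alternate allele, positions stay 1-based, and missing QUAL
#' (".") becomes NA.
#'
#' @param path VCF file path.
#' @return A candidate data.frame (see [variant_candidates()]).
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!length(rr))
    return(variant_candidates(character(), integer(), character(),
                              character()))
  variant_candidates(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    qual = rr$QUAL)
}

#' Write variant candidates as a minimal VCF
#'
#' Emits a VCFv4.2 file with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns
#' (synthetic-data hand-off format; readable back with [read_vcf()]).
#'
#' @param candidates Candidate data.frame.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(candidates, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rows <- if (nrow(candidates))
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.",
            candidates$chrom, candidates$pos, candidates$ref, candidates$alt,
            ifelse(is.na(candidates$qual), ".",
                   format(candidates$qual, trim = TRUE)))
  else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read low-complexity intervals from a BED file
#'
#' BED intervals are 0-based half-open on disk; the returned `GRanges` is
#' 1-based closed (the Bioconductor convention). Intervals are sorted and
#' merged; touching intervals merge too.
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("BED interval with start >= end in ", path)
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Write intervals as BED
#'
#' @param gr A `GRanges` (or data.frame with `chrom`, `start`, `end`,
#'   0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (is.data.frame(gr)) {
    writeLines(sprintf("%s\t%d\t%d", gr$chrom, as.integer(gr$start),
                       as.integer(gr$end)), path)
  } else {
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Assembles and validates the pipeline configuration: locus definitions,
#' a group manifest, and the thresholds used throughout (clone support,
#' variant quality, flank radius, mismatch budget, seed length, homopolymer
#' run, deamination window). Round-trips through YAML unchanged via
#' [write_config()] / [read_config()].
#'
#' @param loci List of locus definitions (each a list with `name`,
#'   `amplicon` or `amplicon_fasta`, `protospacer_start`, `strand`,
#'   `guide_name`, `guide`, optional `window`).
#' @param groups List of group definitions (each a list with `name`,
#'   `locus`, and `fasta`, a clone-pool FASTA whose record names are
#'   `embryoID/cloneID`).
#' @param min_support,min_qual,flank,max_mm,seed_len,min_run,window
#'   Thresholds (defaults 1, 30, 100, 5, 10, 8, c(4, 8)).
#' @param seed Integer seed recorded in outputs.
#' @param outdir Output directory, or NULL to skip writing.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(loci = list(), groups = list(), min_support = 1,
                       min_qual = 30, flank = 100L, max_mm = 5L,
                       seed_len = 10L, min_run = 8L, window = c(4L, 8L),
                       seed = 1L, outdir = NULL) {
  thr <- c(min_support = min_support, min_qual = min_qual, flank = flank,
           max_mm = max_mm, seed_len = seed_len, min_run = min_run)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  window <- as.integer(window)
  if (window[1] < 1L || window[1] > window[2])
    stop("invalid window")
  structure(list(loci = loci, groups = groups,
                 thresholds = list(min_support = min_support,
                                   min_qual = min_qual,
                                   flank = as.integer(flank),
                                   max_mm = as.integer(max_mm),
                                   seed_len = as.integer(seed_len),
                                   min_run = as.integer(min_run),
                                   window = window),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(loci = raw$loci, groups = raw$groups),
                        raw$thresholds,
                        list(seed = raw$seed %||% 1L,
                             outdir = raw$outdir)))
}

# build a target_locus from a config locus entry; paths relative to base_dir
load_locus <- function(entry, base_dir = ".", window = c(4L, 8L)) {
  amplicon <- entry$amplicon
  if (is.null(amplicon)) {
    seqs <- read_fasta(file.path(base_dir, entry$amplicon_fasta))
    amplicon <- if (!is.null(entry$amplicon_record))
      seqs[[entry$amplicon_record]] else seqs[[1L]]
  }
  target_locus(entry$name, amplicon,
               protospacer_start = entry$protospacer_start,
               guide = guide_rna(entry$guide_name %||% entry$name,
                                 entry$guide),
               strand = entry$strand %||% "+",
               window = entry$window %||% window)
}

# split a clone pool (names "embryoID/cloneID") into a per-embryo list
split_pool <- function(seqs) {
  ids <- names(seqs)
  embryo <- sub("/.*$", "", ids)
  split(seqs, factor(embryo, levels = unique(embryo)))
}

#' Run the cohort pipeline from a configuration
#'
#' For every group in the manifest: read the clone-pool FASTA, call alleles
#' per clone, genotype each embryo, and summarise the group; then compute
#' pairwise chi-square comparisons between groups (mutant composition and
#' proximal-of-mutant composition). When `outdir` is set, writes
#' `events.tsv` (one row per clone event), `embryos.tsv` (one row per
#' embryo), `groups.tsv` (Table-2-shaped group summaries) and
#' `chi2_pairwise.tsv`.
#'
#' @param config A `run_config`, or path to its YAML file.
#' @param base_dir Directory against which config file paths are resolved
#'   (defaults to the config file's directory, else `"."`).
#' @return An object of class `becall_report`: list with `genotypes`
#'   (per-group list of `embryo_genotype`), `embryos`, `groups`,
#'   `chi2` data.frames, and a `log` character vector recording the package
#'   version, config hash and per-stage counts.
#' @export
run_pipeline <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- read_config(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  stopifnot(inherits(config, "run_config"))

  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  log <- c(sprintf("becall %s", as.character(utils::packageVersion("becall"))),
           sprintf("config sha: %s", unname(tools::md5sum(cfg_file))))
  unlink(cfg_file)

  loci <- list()
  for (entry in config$loci)
    loci[[entry$name]] <- load_locus(entry, base_dir,
                                     window = config$thresholds$window)

  genotypes <- list()
  embryo_rows <- list()
  event_rows <- list()
  summaries <- list()
  for (grp in config$groups) {
    locus <- loci[[grp$locus]]
    if (is.null(locus))
      stop("[classify] group ", grp$name, ": unknown locus ", grp$locus)
    seqs <- tryCatch(read_fasta(file.path(base_dir, grp$fasta)),
                     error = function(e)
                       stop("[classify] group ", grp$name, ": ",
                            conditionMessage(e), call. = FALSE))
    pools <- split_pool(seqs)
    gts <- lapply(names(pools), function(eid) {
      calls <- classify_pool(locus, pools[[eid]])
      event_rows[[length(event_rows) + 1L]] <<-
        cbind(group = grp$name, embryo_id = eid, events_table(calls),
              stringsAsFactors = FALSE)
      genotype_embryo(calls, embryo_id = eid,
                      min_support = config$thresholds$min_support)
    })
    names(gts) <- names(pools)
    genotypes[[grp$name]] <- gts
    embryo_rows[[grp$name]] <- data.frame(
      group = grp$name,
      embryo_id = names(pools),
      genotype_class = vapply(gts, `[[`, character(1), "genotype_class"),
      is_mutant = vapply(gts, `[[`, logical(1), "is_mutant"),
      is_biallelic = vapply(gts, `[[`, logical(1), "is_biallelic"),
      has_proximal = vapply(gts, `[[`, logical(1), "has_proximal"),
      has_indel = vapply(gts, `[[`, logical(1), "has_indel"),
      n_clones = vapply(gts, function(g) sum(g$distinct_patterns),
                        numeric(1)),
      n_patterns = vapply(gts, function(g) length(g$distinct_patterns),
                          numeric(1)),
      stringsAsFactors = FALSE)
    summaries[[grp$name]] <- summarize_group(grp$name, gts)
    log <- c(log, sprintf("[classify] group %s: %d embryos, %d clones",
                          grp$name, length(pools), length(seqs)))
  }

  embryos <- do.call(rbind, c(embryo_rows, list(make.row.names = FALSE)))
  groups <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  events <- do.call(rbind, c(event_rows, list(make.row.names = FALSE)))
  chi2 <- NULL
  if (!is.null(groups) && nrow(groups) >= 2L) {
    chi2 <- rbind(cbind(comparison = "mutant_vs_not",
                        chi2_pairwise(groups, "mutant")),
                  cbind(comparison = "proximal_vs_not_among_mutant",
                        chi2_pairwise(groups, "proximal_of_mutant")))
  }

  if (!is.null(config$outdir)) {
    dir.create(file.path(base_dir, config$outdir), showWarnings = FALSE,
               recursive = TRUE)
    od <- file.path(base_dir, config$outdir)
    if (!is.null(events)) write_tsv(events, file.path(od, "events.tsv"))
    if (!is.null(embryos)) write_tsv(embryos, file.path(od, "embryos.tsv"))
    if (!is.null(groups)) write_tsv(groups, file.path(od, "groups.tsv"))
    if (!is.null(chi2)) write_tsv(chi2, file.path(od, "chi2_pairwise.tsv"))
    log <- c(log, sprintf("outputs written to %s", od))
  }

  structure(list(genotypes = genotypes, embryos = embryos, groups = groups,
                 events = events, chi2 = chi2, log = log,
                 config = config),
            class = "becall_report")
}

#' @export
print.becall_report <- function(x, ...) {
  cat("<becall_report>\n")
  if (!is.null(x$groups)) {
    cat("  group summaries:\n")
    print(x$groups, row.names = FALSE)
  }
  invisible(x)
}
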