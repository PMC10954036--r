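#' Construct a variant table
#'
#' The shared site coordinate system for the whole pipeline: one row per
#' biallelic SNP, sorted by scaffold then position, with 1-based positions
#' (VCF convention) and a dense 0-based `site_index` within each scaffold.
#'
#' @param scaffold Character vector of scaffold identifiers.
#' @param pos Integer vector of 1-based base-pair positions.
#' @param ref,alt Single-nucleotide reference/alternate alleles.
#' @return A `data.frame` of class `variant_table` with columns
#'   `scaffold`, `pos`, `ref`, `alt`, `site_index`.
#' @export
variant_table <- function(scaffold, pos, ref, alt) {
  stopifnot(length(scaffold) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos))
  if (length(pos) == 0L) stop("variant table is empty")
  ord <- order(match(scaffold, unique(scaffold)), pos)
  scaffold <- as.character(scaffold)[ord]
  pos <- as.integer(pos)[ord]
  ref <- as.character(ref)[ord]
  alt <- as.character(alt)[ord]
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("non-SNP alleles in variant table at row ", which(bad)[1])
  dup <- unlist(tapply(pos, factor(scaffold, levels = unique(scaffold)),
                       function(p) c(FALSE, diff(p) <= 0)), use.names = FALSE)
  if (any(dup)) {
    stop("positions not strictly increasing within scaffold at ",
         scaffold[dup][1], ":", pos[dup][1])
  }
  site_index <- unlist(tapply(pos, factor(scaffold, levels = unique(scaffold)),
                              function(p) seq_along(p) - 1L), use.names = FALSE)
  out <- data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
                    site_index = as.integer(site_index),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Construct a phased haplotype set
#'
#' @param alleles Integer matrix of 0/1 allele codes, one row per haplotype
#'   (two per diploid sample, phase 0 then phase 1), one column per site.
#' @param sample_ids Character vector of sample identifiers, length
#'   `nrow(alleles) / 2`.
#' @return An object of class `hap_set`: a list with elements `alleles`,
#'   `sample_ids` and `haplotype_of_sample` (row -> sample/phase map).
#' @export
hap_set <- function(alleles, sample_ids) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(sample_ids)) {
    stop("haplotype rows (", nrow(alleles), ") must equal 2 x samples (",
         length(sample_ids), ")")
  }
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L))) {
    stop("haplotype alleles must be 0/1 with no missing values")
  }
  hos <- data.frame(sample = rep(sample_ids, each = 2L),
                    phase = rep(c(0L, 1L), length(sample_ids)),
                    stringsAsFactors = FALSE)
  rownames(alleles) <- paste0(hos$sample, "_", hos$phase + 1L)
  structure(list(alleles = alleles, sample_ids = as.character(sample_ids),
                 haplotype_of_sample = hos),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat("hap_set:", nrow(x$alleles), "haplotypes (",
      length(x$sample_ids), "diploids ) x", ncol(x$alleles), "sites\n")
  invisible(x)
}

#' Subset a haplotype set by samples and/or sites
#'
#' @param haps A [hap_set()].
#' @param samples Optional character vector of sample ids to keep.
#' @param sites Optional integer vector of site (column) indices to keep.
#' @export
hap_subset <- function(haps, samples = NULL, sites = NULL) {
  al <- haps$alleles
  ids <- haps$sample_ids
  if (!is.null(samples)) {
    miss <- setdiff(samples, ids)
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    keep <- haps$haplotype_of_sample$sample %in% samples
    al <- al[keep, , drop = FALSE]
    ids <- ids[ids %in% samples]
  }
  if (!is.null(sites)) al <- al[, sites, drop = FALSE]
  hap_set(al, ids)
}

#' Diploid dosage matrix from a haplotype set
#'
#' @param haps A [hap_set()].
#' @return Integer matrix, sites x samples, entries 0/1/2.
#' @export
hap_dosage <- function(haps) {
  n <- length(haps$sample_ids)
  a1 <- haps$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- haps$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  g <- t(a1 + a2)
  colnames(g) <- haps$sample_ids
  g
}

parse_gt_matrix <- function(gt) {
  # gt: character matrix sites x samples, entries like "0|1", "0/1", ".|."
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  miss <- is.na(gt) | a1 == "." | a2 == "." | a2 == ""
  d1 <- suppressWarnings(as.integer(a1))
  d2 <- suppressWarnings(as.integer(a2))
  dos <- d1 + d2
  dos[miss] <- NA_integer_
  dim(dos) <- dim(gt)
  dimnames(dos) <- dimnames(gt)
  list(dosage = dos, a1 = d1, a2 = d2, sep = sep, missing = miss)
}

#' Read a VCF into the pipeline data model
#'
#' Reads phased biallelic SNP genotypes with `vcfR`. Multi-allelic records
#' and indels are skipped (counted, reported via a message), matching the
#' biallelic-SNP filtering the scan assumes. Contig lengths present in the
#' header are captured as scaffold lengths.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param haplotypes If `TRUE` (default), require fully phased, non-missing
#'   GT fields and return a [hap_set()]; the first offending sample/site is
#'   named otherwise. If `FALSE` only the diploid dosage matrix is built and
#'   missing genotypes are allowed.
#' @return A list with elements `variants` ([variant_table()]),
#'   `haplotypes` (`hap_set` or `NULL`), `genotypes` (dosage matrix,
#'   sites x samples, `NA` allowed when `haplotypes = FALSE`),
#'   `scaffolds` (named lengths or `NULL`) and `n_skipped`.
#' @export
read_vcf <- function(path, haplotypes = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("empty VCF: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s) in ", basename(path))
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  variants <- variant_table(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                            ref[keep], alt[keep])
  # variant_table may reorder; apply the same order to genotypes
  ord <- order(match(fix[keep, "CHROM"], unique(fix[keep, "CHROM"])),
               as.integer(fix[keep, "POS"]))
  gt <- gt[ord, , drop = FALSE]
  parsed <- parse_gt_matrix(gt)
  rownames(parsed$dosage) <- paste0(variants$scaffold, ":", variants$pos)
  haps <- NULL
  if (haplotypes) {
    bad <- which(parsed$missing | parsed$sep != "|")
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(gt))
      stop("unphased or missing genotype for sample ", colnames(gt)[i[2]],
           " at ", variants$scaffold[i[1]], ":", variants$pos[i[1]],
           " (haplotype output requires fully phased calls)")
    }
    n_s <- ncol(gt)
    al <- matrix(0L, nrow = 2L * n_s, ncol = nrow(gt))
    al[seq(1L, 2L * n_s, by = 2L), ] <- t(matrix(parsed$a1, nrow(gt), n_s))
    al[seq(2L, 2L * n_s, by = 2L), ] <- t(matrix(parsed$a2, nrow(gt), n_s))
    haps <- hap_set(al, colnames(gt))
  }
  scaffolds <- scaffolds_from_meta(v@meta)
  list(variants = variants, haplotypes = haps, genotypes = parsed$dosage,
       scaffolds = scaffolds, n_skipped = n_skipped)
}

scaffolds_from_meta <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", ln)
  has_len <- grepl("length=", ln)
  len <- rep(NA_real_, length(ln))
  len[has_len] <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ln[has_len]))
  stats::setNames(len, id)
}

#' Write a phased haplotype set as a VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields ("|" separator) so that
#' `read_vcf(write_vcf(...))` round-trips the allele matrix exactly.
#'
#' @param path Output path (plain text).
#' @param variants A [variant_table()].
#' @param haplotypes A [hap_set()] over the same sites.
#' @param scaffolds Optional named vector of scaffold lengths for contig
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, variants, haplotypes, scaffolds = NULL) {
  stopifnot(inherits(variants, "variant_table"), inherits(haplotypes, "hap_set"))
  if (ncol(haplotypes$alleles) != nrow(variants)) {
    stop("haplotype sites (", ncol(haplotypes$alleles),
         ") do not match variant table rows (", nrow(variants), ")")
  }
  meta <- c("##fileformat=VCFv4.2",
            "##source=sweepscanr",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(scaffolds)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(scaffolds), as.integer(scaffolds)))
  }
  n <- length(haplotypes$sample_ids)
  a1 <- haplotypes$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- haplotypes$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt_cols <- vapply(seq_len(n), function(i) {
    paste0(a1[i, ], "|", a2[i, ])
  }, character(nrow(variants)))
  if (nrow(variants) == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  body <- paste(variants$scaffold, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", haplotypes$sample_ids), collapse = "\t")
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Read a two-column sample-to-population map
#'
#' @param path Tab-separated file: sample id, population label. No header.
#' @param vcf_samples Optional character vector of samples that must all be
#'   covered (typically the VCF sample list); uncovered samples are an error,
#'   popmap-only samples a warning.
#' @param pops Optional population pair to restrict to; samples with other
#'   labels are dropped with a message.
#' @return `data.frame` with columns `sample`, `pop`; attribute
#'   `populations` holds the ordered unique labels.
#' @export
read_popmap <- function(path, vcf_samples = NULL, pops = NULL) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "pop"),
                          colClasses = "character")
  popmap(pm$sample, pm$pop, vcf_samples = vcf_samples, pops = pops)
}

#' Build and validate a population map
#'
#' @param sample,pop Parallel character vectors.
#' @inheritParams read_popmap
#' @export
popmap <- function(sample, pop, vcf_samples = NULL, pops = NULL) {
  pm <- data.frame(sample = as.character(sample), pop = as.character(pop),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$sample)) {
    d <- pm[pm$sample %in% pm$sample[duplicated(pm$sample)], ]
    if (any(tapply(d$pop, d$sample, function(x) length(unique(x))) > 1L)) {
      stop("conflicting population labels for sample(s): ",
           paste(unique(d$sample), collapse = ", "))
    }
    pm <- pm[!duplicated(pm$sample), ]
  }
  if (!is.null(pops)) {
    drop <- !(pm$pop %in% pops)
    if (any(drop)) {
      message("popmap: dropping ", sum(drop),
              " sample(s) outside populations ", paste(pops, collapse = "/"))
      pm <- pm[!drop, , drop = FALSE]
    }
  }
  if (!is.null(vcf_samples)) {
    missing <- setdiff(vcf_samples, pm$sample)
    if (length(missing)) {
      stop("sample(s) in VCF absent from popmap: ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(pm$sample, vcf_samples)
    if (length(extra)) {
      warning("popmap contains sample(s) not in VCF: ",
              paste(extra, collapse = ", "))
    }
  }
  counts <- table(pm$pop)
  if (any(counts < 2L)) {
    stop("population(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  attr(pm, "populations") <- unique(pm$pop)
  pm
}

#' Write a popmap as two-column TSV
#' @param pm Population map.
#' @param path Output path.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm[, c("sample", "pop")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read scaffold lengths from a two-column TSV
#'
#' @param path Tab-separated file: scaffold id, length in bp. No header.
#' @return Named numeric vector of lengths.
#' @export
read_scaffold_lengths <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("scaffold", "length"))
  stats::setNames(as.numeric(x$length), x$scaffold)
}

#' Write scaffold lengths as two-column TSV
#' @param scaffolds Named vector of lengths.
#' @param path Output path.
#' @export
write_scaffold_lengths <- function(scaffolds, path) {
  utils::write.table(data.frame(names(scaffolds), as.integer(scaffolds)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_scaffolds <- function(scaffolds, variants) {
  miss <- setdiff(unique(variants$scaffold), names(scaffolds))
  if (length(miss)) {
    stop("scaffold(s) in variant table without a length: ",
         paste(miss, collapse = ", "))
  }
  mx <- tapply(variants$pos, variants$scaffold, max)
  short <- names(mx)[scaffolds[names(mx)] < mx]
  if (length(short)) {
    stop("scaffold length smaller than max SNP position for: ",
         paste(short, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write candidate regions as TSV or BED
#'
#' Internally all regions are 1-based inclusive (VCF-style, the convention
#' reported intervals use). The BED dialect converts to 0-based half-open at
#' the boundary; the header line states the dialect in use.
#'
#' @param regions `data.frame` with at least `scaffold`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @param dialect `"tsv"` (1-based inclusive) or `"bed"` (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (nrow(regions) > 0 && any(regions$start > regions$end)) {
    stop("region start > end")
  }
  if (dialect == "bed") {
    hdr <- "# coordinates: 0-based half-open (BED)"
    out <- regions
    out$start <- out$start - 1L
    first <- c("scaffold", "start", "end")
  } else {
    hdr <- "# coordinates: 1-based inclusive (TSV)"
    out <- regions
    first <- c("scaffold", "start", "end")
  }
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a regions file written by [write_regions()]
#'
#' Coordinates are converted back to the internal 1-based inclusive
#' convention regardless of dialect.
#' @param path Path to a TSV/BED regions file with a dialect header line.
#' @export
read_regions <- function(path) {
  hdr <- readLines(path, n = 1L)
  x <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                         stringsAsFactors = FALSE)
  if (grepl("BED", hdr)) x$start <- x$start + 1L
  x
}
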