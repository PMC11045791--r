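#' Write a panel call set as VCF v4.2
#'
#' Serialises the variant annotation table and per-sample genotype/depth
#' matrices into a plain-text VCF with the panel annotations carried in
#' INFO (`GENE`, `GROUP`, `REGION`, `CANONICAL`, `CADD`, `HGVSP`, and the
#' QC warning flags `LC`, `PW`, `LQ`) and `GT:DP` per sample.
#'
#' @param variants Variant annotation tibble from [simulate_panel()].
#' @param gt,dp Samples x variants dosage and depth matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(variants, gt, dp, path) {
  samples <- rownames(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=agrivar",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
    "##INFO=<ID=GROUP,Number=1,Type=Integer,Description=\"Gene selection group (1-5)\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class (exonic/splice/other)\">",
    "##INFO=<ID=CANONICAL,Number=1,Type=Integer,Description=\"On canonical transcript (1/0)\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"Scaled CADD score\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein notation\">",
    "##INFO=<ID=LC,Number=0,Type=Flag,Description=\"Low complexity region\">",
    "##INFO=<ID=PW,Number=0,Type=Flag,Description=\"Phasing warning\">",
    "##INFO=<ID=LQ,Number=0,Type=Flag,Description=\"Low quality warning\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))

  info <- sprintf(
    "GENE=%s;GROUP=%d;REGION=%s;CANONICAL=%d;CADD=%s;HGVSP=%s%s%s%s",
    variants$gene, variants$group, variants$region,
    as.integer(variants$canonical),
    ifelse(is.na(variants$cadd), ".", as.character(variants$cadd)),
    variants$hgvs_p,
    ifelse(variants$low_complexity, ";LC", ""),
    ifelse(variants$phase_warning, ";PW", ""),
    ifelse(variants$lowq_warning, ";LQ", ""))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[t(gt) + 1L], nrow = ncol(gt))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, as.character(variants$qual),
                variants$filter, info, "GT:DP", sep = "\t")
  calls <- matrix(paste(gt_str, t(dp), sep = ":"), nrow = ncol(gt))
  body <- paste(body, apply(calls, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a panel VCF back into the pipeline's tables
#'
#' Parses a VCF written by [write_panel_vcf()] (or any VCF carrying the
#' same INFO/FORMAT fields) via `vcfR` and rebuilds the variant annotation
#' tibble and the genotype/depth matrices.
#'
#' @param path VCF file path.
#' @return A list with `variants`, `gt`, `dp`.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  info_flag <- function(key) {
    grepl(paste0("(^|;)", key, "(;|$)"), fix$INFO)
  }
  cadd <- info_get("CADD")
  variants <- tibble(
    variant_id = fix$ID,
    chrom = as.integer(fix$CHROM), pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    hgvs_p = info_get("HGVSP"),
    gene = info_get("GENE"),
    group = as.integer(info_get("GROUP")),
    region = info_get("REGION"),
    canonical = info_get("CANONICAL") == "1",
    cadd = suppressWarnings(as.numeric(ifelse(cadd == ".", NA, cadd))),
    qual = as.numeric(fix$QUAL), filter = fix$FILTER,
    low_complexity = info_flag("LC"),
    phase_warning = info_flag("PW"),
    lowq_warning = info_flag("LQ"))

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp_chr <- vcfR::extract.gt(v, element = "DP")
  dose <- matrix(match(gt_chr, c("0/0", "0/1", "1/1")) - 1L,
                 nrow = nrow(gt_chr), dimnames = dimnames(gt_chr))
  gt <- t(dose)
  dp <- t(matrix(as.integer(dp_chr), nrow = nrow(dp_chr),
                 dimnames = dimnames(dp_chr)))
  colnames(gt) <- colnames(dp) <- variants$variant_id
  list(variants = variants, gt = gt, dp = dp)
}
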