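# Variant catalogs: GWAS association records (risk variants), population
# variants with minor allele frequency (benign candidates), and
# identifier -> position lookup.
#
# A catalog is a data.frame with columns:
#   id     character, unique
#   chrom  character
#   pos    integer, 1-based
#   maf    numeric in [0, 0.5] or NA
#   traits character, semicolon-joined trait labels ("" = none)

new_variant_catalog <- function(df) {
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (is.null(df$maf)) df$maf <- NA_real_
  df$maf <- as.numeric(df$maf)
  if (is.null(df$traits)) df$traits <- ""
  df$traits <- ifelse(is.na(df$traits), "", as.character(df$traits))
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1]
    stop(sprintf("duplicate variant id '%s' in catalog", dup))
  }
  bad_maf <- !is.na(df$maf) & (df$maf < 0 | df$maf > 0.5)
  if (any(bad_maf)) stop("maf outside [0, 0.5]")
  rownames(df) <- NULL
  class(df) <- c("variant_catalog", "data.frame")
  df
}

#' Build a variant catalog from vectors
#'
#' @param id,chrom,pos vectors of identifier, chromosome and 1-based
#'   position; recycled as in `data.frame`.
#' @param maf minor allele frequency in `[0, 0.5]`, `NA` when unknown.
#' @param traits character vector of semicolon-joined trait labels; `""`
#'   means the variant has no catalogued association.
#' @return a `variant_catalog` (a data.frame subclass).
#' @export
variant_catalog <- function(id, chrom, pos, maf = NA_real_, traits = "") {
  new_variant_catalog(data.frame(id = id, chrom = chrom, pos = pos,
                                 maf = maf, traits = traits,
                                 stringsAsFactors = FALSE))
}

#' @export
print.variant_catalog <- function(x, ...) {
  n_assoc <- sum(nzchar(x$traits))
  cat(sprintf("variant catalog: %d variants (%d with trait associations)\n",
              nrow(x), n_assoc))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

split_traits <- function(traits) {
  strsplit(ifelse(nzchar(traits), traits, NA_character_), ";", fixed = TRUE)
}

#' Load a variant catalog from file
#'
#' Tab-delimited catalogs have columns `id`, `chrom`, `pos` and optionally
#' `maf` and semicolon-joined `traits`; a header line starting with `id` and
#' `#`-comment lines are ignored. VCF input (`*.vcf`, `*.vcf.gz`) takes
#' `CHROM`/`POS`/`ID`, with MAF parsed from the `AF` or `MAF` INFO field
#' when present (allele frequencies above 0.5 are folded to the minor
#' allele). Malformed lines are skipped with a warning giving their count.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a `variant_catalog`.
#' @export
load_catalog <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read catalog '%s'", path))
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") load_catalog_vcf(path) else load_catalog_tsv(path)
}

load_catalog_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "id\t")]
  if (length(lines) == 0) stop("empty catalog")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  pos_chr <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                    character(1))
  pos_num <- suppressWarnings(as.numeric(pos_chr))
  ok <- nf >= 3 & !is.na(pos_num) & pos_num >= 1
  if (any(!ok))
    ds_warn("load_catalog: skipped %d malformed line(s) in '%s'",
            sum(!ok), path)
  fields <- fields[ok]
  if (length(fields) == 0) stop("empty catalog")
  get_col <- function(k) vapply(fields, function(f)
    if (length(f) >= k && nzchar(f[k])) f[k] else NA_character_, character(1))
  maf <- suppressWarnings(as.numeric(get_col(4)))
  traits <- get_col(5)
  new_variant_catalog(data.frame(
    id = get_col(1), chrom = get_col(2), pos = as.numeric(pos_chr[ok]),
    maf = maf, traits = ifelse(is.na(traits), "", traits),
    stringsAsFactors = FALSE
  ))
}

load_catalog_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("empty catalog")
  info <- vcfR::getINFO(v)
  parse_af <- function(s) {
    m <- regmatches(s, regexec("(?:^|;)(?:AF|MAF)=([0-9.eE+-]+)", s))
    vapply(m, function(x) if (length(x) == 2) as.numeric(x[2]) else NA_real_,
           numeric(1))
  }
  af <- parse_af(info)
  maf <- ifelse(!is.na(af) & af > 0.5, 1 - af, af)
  id <- fix[, "ID"]
  miss <- is.na(id) | id == "."
  if (any(miss))
    id[miss] <- paste0(fix[miss, "CHROM"], ":", fix[miss, "POS"])
  new_variant_catalog(data.frame(
    id = id, chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    maf = maf, traits = "", stringsAsFactors = FALSE
  ))
}

#' Risk variants for a trait
#'
#' Returns the variants whose trait annotations contain `trait`
#' (exact, case-insensitive match of the full label; no ontology
#' expansion). These form the positive training set.
#'
#' @param catalog a `variant_catalog`.
#' @param trait trait label, e.g. `"Behcet Syndrome"`.
#' @return a `variant_catalog` of the matching variants.
#' @export
risk_set <- function(catalog, trait) {
  stopifnot(inherits(catalog, "variant_catalog"))
  if (!is.character(trait) || length(trait) != 1 || !nzchar(trait))
    stop("trait name must be a non-empty string")
  tl <- tolower(trait)
  hit <- vapply(split_traits(catalog$traits), function(t)
    !all(is.na(t)) && tl %in% tolower(t), logical(1))
  if (!any(hit)) stop(sprintf("no risk variants for trait '%s'", trait))
  out <- catalog[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benign candidate variants
#'
#' Common variants eligible for the negative set: MAF strictly greater than
#' `maf_min` and no association record in `association_catalog` — matched
#' by id first, then by (chrom, pos) — with a non-empty trait set.
#'
#' @param catalog population `variant_catalog` with MAF.
#' @param maf_min MAF threshold, strict (default 0.05).
#' @param association_catalog catalog of known associations to exclude
#'   against.
#' @return a `variant_catalog` of candidates (possibly empty, with a
#'   warning).
#' @export
benign_candidates <- function(catalog, maf_min = 0.05,
                              association_catalog = NULL) {
  stopifnot(inherits(catalog, "variant_catalog"))
  if (!(maf_min >= 0 && maf_min < 0.5)) stop("maf_min must be in [0, 0.5)")
  keep <- !is.na(catalog$maf) & catalog$maf > maf_min
  if (!is.null(association_catalog)) {
    assoc <- association_catalog[nzchar(association_catalog$traits), ,
                                 drop = FALSE]
    by_id <- catalog$id %in% assoc$id
    by_pos <- paste(catalog$chrom, catalog$pos) %in%
      paste(assoc$chrom, assoc$pos)
    keep <- keep & !by_id & !by_pos
  }
  if (!any(keep))
    ds_warn("benign_candidates: no variant passes MAF > %g and the association filter",
            maf_min)
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up variants by identifier
#'
#' @param ids character vector of identifiers; duplicates are preserved,
#'   one output row each, in input order.
#' @param catalog a `variant_catalog`.
#' @return list with `matched` (a `variant_catalog`, rows in input order)
#'   and `unmatched` (character vector of ids not in the catalog).
#' @export
lookup_ids <- function(ids, catalog) {
  stopifnot(inherits(catalog, "variant_catalog"))
  ids <- as.character(ids)
  i <- match(ids, catalog$id)
  matched <- catalog[i[!is.na(i)], , drop = FALSE]
  rownames(matched) <- NULL
  list(matched = matched, unmatched = ids[is.na(i)])
}

#' Write a catalog in the package's tab-delimited format
#'
#' @param catalog a `variant_catalog`.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$maf <- ifelse(is.na(df$maf), "", format(df$maf, trim = TRUE, digits = 15))
  utils::write.table(df[, c("id", "chrom", "pos", "maf", "traits")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
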