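# ---- score file ----------------------------------------------------------

#' Write a score definition as tab-separated text
#'
#' Minimal PGS-catalog-like dialect with header
#' `chrom pos ref alt effect_allele weight`. Weights are written with 17
#' significant digits so they round-trip bit-identically.
#'
#' @param score A `score_definition`.
#' @param path Output path.
#' @export
write_score_file <- function(score, path) {
  stopifnot(inherits(score, "score_definition"))
  df <- score
  class(df) <- "data.frame"
  df$weight <- sprintf("%.17g", score$weight)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated score file
#'
#' @param path File written by [write_score_file()] (or any file with the
#'   same columns).
#' @return A `score_definition`.
#' @export
read_score_file <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", pos = "integer",
                                  ref = "character", alt = "character",
                                  effect_allele = "character",
                                  weight = "numeric"))
  need <- c("chrom", "pos", "ref", "alt", "effect_allele", "weight")
  if (!all(need %in% names(df)))
    stop("score file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(df$chrom, df$pos, df$ref, df$alt)))
    stop("duplicate sites in score file")
  class(df) <- c("score_definition", "data.frame")
  df
}

# ---- genetic map ---------------------------------------------------------

#' Write the genetic map as 3-column tab-separated text
#'
#' Columns `chrom pos cM` (cumulative genetic position per site).
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @export
write_genetic_map <- function(panel, path) {
  df <- data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
                   cM = sprintf("%.8f", panel$cum_cm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3-column genetic map
#'
#' @param path Tab-separated file with columns `chrom pos cM`.
#' @return Data frame with cumulative centiMorgan positions.
#' @export
read_genetic_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "cM") %in% names(df)))
    stop("genetic map must have columns: chrom pos cM")
  df
}

# ---- VCF -----------------------------------------------------------------

vcf_meta <- function(extra = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=lcgps",
    "##contig=<ID=chrS>",
    extra)
}

make_vcfR <- function(sites, info, format_id, gt_body, sample_ids, meta_extra) {
  fix <- cbind(CHROM = as.character(sites$chrom), POS = as.character(sites$pos),
               ID = ".", REF = sites$ref, ALT = sites$alt, QUAL = ".",
               FILTER = "PASS", INFO = info)
  gt <- cbind(FORMAT = format_id, gt_body)
  colnames(gt) <- c("FORMAT", sample_ids)
  new("vcfR", meta = vcf_meta(meta_extra), fix = fix, gt = gt)
}

#' Write a phased haplotype panel as VCF
#'
#' Phased GT (pipe separator); per-population alternate-allele frequencies
#' are stored in INFO as a comma-joined `PAF` tag whose order is declared in
#' a `##POPS=` header line.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path (a `.gz` suffix writes a compressed file).
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  pops <- sub("^af_", "", grep("^af_", names(panel$sites), value = TRUE))
  af <- as.matrix(panel$sites[paste0("af_", pops)])
  info <- paste0("PAF=", apply(round(af, 6), 1L, paste, collapse = ","))
  n <- length(panel$sample_ids)
  h1 <- t(panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE])
  h2 <- t(panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE])
  body <- matrix(paste0(h1, "|", h2), nrow(panel$sites), n)
  v <- make_vcfR(panel$sites, info, "GT", body, panel$sample_ids,
                 c(sprintf("##POPS=%s", paste(pops, collapse = ",")),
                   "##INFO=<ID=PAF,Number=.,Type=Float,Description=\"Per-population ALT allele frequency\">",
                   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write unphased genotypes (truth or array calls) as VCF
#'
#' Missing genotypes become `./.`.
#'
#' @param x A `truth_genotypes` or `array_genotypes`.
#' @param path Output path.
#' @export
write_genotype_vcf <- function(x, path) {
  if (inherits(x, "array_genotypes")) {
    sites <- x$sites; G <- x$genotypes; ids <- x$sample_ids
  } else if (inherits(x, "truth_genotypes")) {
    sites <- x$sites; G <- x$genotypes; ids <- x$sample_ids
  } else stop("expected `truth_genotypes` or `array_genotypes`")
  code <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow(sites), nrow(G))
  ok <- !is.na(t(G))
  body[ok] <- code[t(G)[ok] + 1L]
  v <- make_vcfR(sites, ".", "GT", body, ids,
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write imputed dosages as VCF
#'
#' FORMAT fields `GT` (posterior argmax when posteriors are available,
#' otherwise rounded dosage), `DS` (dosage, 3 decimals) and `GP` (posterior
#' triplet) when posteriors were kept. Sites covered by no read in any
#' sample carry the INFO flag `IMPUTED`.
#'
#' @param dosages A `dosage_matrix`.
#' @param path Output path.
#' @export
write_dosage_vcf <- function(dosages, path) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  D <- dosages$dosage
  m <- ncol(D); n <- nrow(D)
  covered_any <- rep(FALSE, m)
  for (cv in dosages$covered) covered_any[cv] <- TRUE
  info <- ifelse(covered_any, ".", "IMPUTED")
  code <- c("0/0", "0/1", "1/1")
  has_gp <- !is.null(dosages$posterior)
  if (has_gp) {
    P <- dosages$posterior
    gt_call <- apply(P, c(1, 2), which.max)
    body <- matrix("", m, n)
    for (i in seq_len(n))
      body[, i] <- sprintf("%s:%.3f:%.3f,%.3f,%.3f", code[gt_call[i, ]],
                           D[i, ], P[i, , 1], P[i, , 2], P[i, , 3])
    fmt <- "GT:DS:GP"
  } else {
    body <- matrix("", m, n)
    for (i in seq_len(n))
      body[, i] <- sprintf("%s:%.3f", code[pmin(2L, pmax(0L, round(D[i, ]))) + 1L],
                           D[i, ])
    fmt <- "GT:DS"
  }
  v <- make_vcfR(dosages$sites, info, fmt, body, dosages$sample_ids,
                 c("##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"No read in any sample\">",
                   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                   "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
                   "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior\">"))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write genotype likelihoods as VCF
#'
#' FORMAT `GP` carries the normalized likelihood triplet; entries are
#' missing (`.`) at sites a sample has no retained read for. Only sites
#' covered in at least one sample are written.
#'
#' @param gls A `gl_set` from [compute_gl()].
#' @param path Output path.
#' @export
write_gl_vcf <- function(gls, path) {
  stopifnot(inherits(gls, "gl_set"))
  covered_any <- sort(unique(unlist(lapply(gls$samples, `[[`, "covered"))))
  if (length(covered_any) == 0L) stop("no covered sites to write")
  n <- length(gls$samples)
  body <- matrix(".", length(covered_any), n)
  for (i in seq_len(n)) {
    s <- gls$samples[[i]]
    lik <- s$lik / rowSums(s$lik)
    body[match(s$covered, covered_any), i] <-
      sprintf("%.4f,%.4f,%.4f", lik[, 1], lik[, 2], lik[, 3])
  }
  v <- make_vcfR(gls$sites[covered_any, , drop = FALSE], ".", "GP", body,
                 gls$sample_ids,
                 "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Normalized genotype likelihood\">")
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF and dispatch on its content
#'
#' Phased GT records become a `haplotype_panel` (per-population allele
#' frequencies recovered from the `PAF` INFO tag when present); unphased GT
#' becomes `truth_genotypes`; a `DS` FORMAT field becomes a
#' `dosage_matrix`. Multiallelic records are rejected with the offending
#' position (split them into biallelic records first). VCF POS is 1-based;
#' the first record maps to in-memory site index 1.
#'
#' @param path VCF path (plain or gzipped).
#' @return A `haplotype_panel`, `truth_genotypes` or `dosage_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop("VCF contains no records")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multiallelic record at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"],
         "; split into biallelic records before import")
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  fmt <- v@gt[1, "FORMAT"]
  ids <- colnames(v@gt)[-1]
  if (grepl("DS", fmt)) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    D <- t(ds)
    dimnames(D) <- list(ids, NULL)
    return(structure(list(dosage = D, sites = sites, sample_ids = ids,
                          covered = list(), posterior = NULL,
                          provenance = list(stage = "vcf-import")),
                     class = "dosage_matrix"))
  }
  gt <- vcfR::extract.gt(v)   # sites x samples, e.g. "0|1" or "0/1"
  phased <- all(grepl("|", gt, fixed = TRUE), na.rm = TRUE) && !anyNA(gt)
  if (phased) {
    a1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt)))
    a2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt)))
    n <- length(ids)
    haps <- matrix(0L, 2L * n, nrow(sites))
    haps[seq(1L, 2L * n, 2L), ] <- a1
    haps[seq(2L, 2L * n, 2L), ] <- a2
    pops_line <- grep("^##POPS=", v@meta, value = TRUE)
    paf <- vcfR::extract.info(v, "PAF")
    if (length(pops_line) == 1L && !all(is.na(paf))) {
      pops <- strsplit(sub("^##POPS=", "", pops_line), ",")[[1]]
      af <- do.call(rbind, lapply(strsplit(paf, ","), as.numeric))
      colnames(af) <- paste0("af_", pops)
      sites <- cbind(sites, as.data.frame(af))
    }
    sites$af_global <- colMeans(haps)
    sites$maf <- pmin(sites$af_global, 1 - sites$af_global)
    cum_cm <- sites$pos / 1e6   # default 1 cM/Mb map; replace via read_genetic_map
    structure(list(sites = sites, haplotypes = haps, sample_ids = ids,
                   population_of = stats::setNames(rep(NA_character_, n), ids),
                   genetic_map = diff(cum_cm), cum_cm = cum_cm,
                   pedigree = stats::setNames(vector("list", n), ids),
                   config = NULL), class = "haplotype_panel")
  } else {
    alt_count <- function(s) {
      if (is.na(s)) return(NA_integer_)
      as.integer(substr(s, 1, 1)) + as.integer(substr(s, 3, 3))
    }
    G <- t(matrix(vapply(gt, alt_count, integer(1)), nrow(gt), ncol(gt)))
    dimnames(G) <- list(ids, NULL)
    structure(list(sample_ids = ids, genotypes = G, haplotypes = NULL,
                   sites = sites, population_of = NULL, relative_of = list()),
              class = "truth_genotypes")
  }
}

# ---- run configuration and provenance ------------------------------------

default_run_config <- function() {
  list(seed = 1L,
       panel = list(n_founders = 50L, n_panel_samples = 250L, n_sites = 4500L,
                    region_length_bp = 1e7, cm_per_mb = 1.0,
                    mosaic_switch_rate = 1.0, mutation_miscopy_rate = 1e-3,
                    drift = 0.05, maf_filter_threshold = 0.01),
       reads = list(coverage = 0.5, base_error = 0.005, frac_other = 0.002),
       ladder = c(2, 1, 0.75, 0.5, 0.4, 0.25, 0.1),
       hmm = list(lambda = 1e-3, scale = 2),
       panel_size = 250L,
       n_targets = 20L,
       thresholds = list(coverage_qc = 0.5, call_rate = 0.97,
                         missingness = 0.05, hwe_alpha = 1e-6),
       n_pcs = 10L)
}

#' Read a YAML run configuration
#'
#' Missing keys fall back to package defaults except the required keys,
#' whose absence is an error naming the key.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (key in c("seed"))
      if (is.null(user[[key]]))
        stop(sprintf("run config is missing required key `%s`", key))
    cfg <- modifyList(cfg, user)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write a run configuration as YAML
#' @param config A `run_config` (or plain list).
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a machine-readable provenance record
#'
#' JSON with the configuration, its hash, the seed, the package version and
#' a timestamp; one per CLI run, next to the run's outputs.
#'
#' @param config The `run_config` used.
#' @param path Output path.
#' @param extra Named list of additional fields.
#' @export
write_provenance <- function(config, path, extra = list()) {
  cfg <- unclass(config)
  rec <- c(list(config = cfg,
                config_hash = config_hash(cfg),
                seed = cfg$seed,
                package = "lcgps",
                version = as.character(utils::packageVersion("lcgps")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# deterministic short hash of a config list (no external digest dependency)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  raw <- utils::head(charToRaw(s), 1e5)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
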