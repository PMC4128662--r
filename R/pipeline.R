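# End-to-end orchestration: filter -> mask -> classify -> diversity ->
# structure -> LD -> PHS, with a reproducibility manifest.

#' Default pipeline parameters
#'
#' Window scans default to 20 kb/4 kb, call filters to quality 30 and depth
#' 10 with a mean + 3 SD per-sample depth cap, LD to a 10\% MAF floor and a
#' 1-100 kb fit range, SNP thinning to 50 kb spacing, PHS to a quartic
#' genetic map, a 30 kb missing-cluster threshold and a top 0.1\% candidate
#' fraction.
#'
#' @return named list of parameters
#' @export
pipeline_defaults <- function() {
  list(window_size = 20000L, window_step = 4000L,
       min_qual = 30, min_depth = 10, depth_sd_factor = 3,
       depth_rule = "mean_plus_3sd",
       maf_min = 0.10, ld_max_dist = 500000L, ld_bin_size = 1000L,
       fit_min = 1000, fit_max = 100000,
       thin_spacing = 50000L, top_fraction = 0.001,
       miss_cluster_bp = 30000L, map_degree = 4L,
       strict_intergenic_flank = 0L, seed = 1L)
}

#' Run the full analysis pipeline
#'
#' @param config list (or path to a YAML file) with input paths
#'   (\code{fasta}, \code{vcf}, optional \code{callable_bed}, \code{gff},
#'   \code{markers}), an \code{out_dir}, and any parameter overrides of
#'   \code{\link{pipeline_defaults}}
#' @return invisible list of stage results; tables, trees and the manifest
#'   are written to \code{out_dir}
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  par <- utils::modifyList(pipeline_defaults(), config)
  for (key in c("fasta", "vcf", "out_dir"))
    if (is.null(par[[key]])) stop("config is missing '", key, "'")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ref <- stage("io", read_reference(par$fasta))
  gm <- stage("io", read_variants(par$vcf, ref))
  ann <- if (!is.null(par$gff)) stage("io", read_annotation(par$gff))
  callable <- if (!is.null(par$callable_bed))
    stage("io", read_callable_bed(par$callable_bed))
  gm <- stage("filter-calls",
              filter_calls(gm, min_qual = par$min_qual,
                           min_depth = par$min_depth,
                           depth_sd_factor = par$depth_sd_factor,
                           depth_rule = par$depth_rule))
  mask <- stage("mask", build_site_mask(ref, annotation = ann))
  am <- stage("mask", apply_mask_and_complete(gm, mask, ref,
                                              callable = callable))
  results <- list(mask = as.data.frame(mask))
  if (!is.null(ann)) {
    cmap <- stage("classify",
                  classify_sites(ann, ref, am,
                                 strict_intergenic_flank =
                                   par$strict_intergenic_flank))
    results$class_diversity <- stage("diversity", class_diversity(am, cmap))
    genes <- names(cmap$genes)[vapply(cmap$genes, function(g)
      isTRUE(g$ok), TRUE)]
    results$gene_diversity <- stage("diversity", do.call(rbind,
      lapply(genes, function(g) tryCatch(gene_diversity(g, am, cmap),
                                         error = function(e) NULL))))
  }
  results$windows <- stage("diversity",
                           window_scan(am, par$window_size, par$window_step))
  spec <- stage("diversity", minor_allele_spectrum(am))
  results$maf_spectrum <- data.frame(minor_count = as.integer(names(spec$counts)),
                                     n_sites = as.integer(spec$counts))
  d <- stage("structure", p_distance_matrix(am))
  results$p_distance <- d
  results$nj_tree <- stage("structure", neighbor_joining(d))
  thin <- stage("structure", thin_snps(am, par$thin_spacing, seed = par$seed))
  results$thinned_snps <- data.frame(chrom = am$sites$chrom[thin],
                                     pos = am$sites$pos[thin])
  if (length(thin) >= 2L) {
    pca <- stage("structure", pca_genotypes(am, thin))
    results$pca_coords <- pca$coords
    results$pca_eigenvalues <- data.frame(component = seq_along(pca$eigenvalues),
                                          eigenvalue = pca$eigenvalues)
  }
  pairs <- stage("ld", pairwise_r2(am, maf_min = par$maf_min,
                                   max_dist = par$ld_max_dist))
  if (nrow(pairs) > 0L) {
    decay <- stage("ld", bin_ld_decay(pairs, par$ld_bin_size))
    results$ld_decay <- as.data.frame(decay)
    rho <- tryCatch(estimate_rho(decay, par$fit_min, par$fit_max),
                    error = function(e) NULL)
    if (!is.null(rho)) results$rho_estimate <- unclass(rho)
  }
  if (!is.null(par$markers)) {
    mk <- stage("phs", read_marker_table(par$markers))
    map <- stage("phs", fit_genetic_map(mk, degree = par$map_degree))
    results$phs <- stage("phs",
                         phs_scan(am, map, top_fraction = par$top_fraction,
                                  miss_cluster_bp = par$miss_cluster_bp))
  } else if (isTRUE(par$require_phs)) {
    stop("pipeline stage 'phs' failed: no marker table configured")
  }
  files <- write_tables(results[!vapply(results, is.null, TRUE)],
                        par$out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("haploscan")),
    parameters = par[setdiff(names(par), "out_dir")],
    inputs = lapply(par[intersect(c("fasta", "vcf", "callable_bed", "gff",
                                    "markers"), names(par))],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    n_samples = length(am$samples), n_snps = n_sites(am),
    called_sites = called_sites(am))
  jsonlite::write_json(manifest, file.path(par$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
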