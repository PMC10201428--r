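# Orchestration: a single structured configuration drives a deterministic
# demo run of the full pipeline (design -> simulate -> quantify -> report),
# and every emitted table carries a provenance header (package version,
# seed, configuration fingerprint).

#' Default pipeline configuration
#'
#' All fixed analysis constants with their standard values: the 19-nt
#' barcode-extraction primer, the 43-56 bp integration-distance window,
#' logo parameters (four-fold enrichment threshold, top 5000 sequences per
#' library), the 5-nt TSD length, and demo-scale simulation sizes.
#'
#' @param seed master seed for the run.
#' @return nested named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    anchors = list(primer19 = donor_primer19()),
    distance_window = c(43L, 56L),
    tsd_length = 5L,
    logo = list(threshold = 4, top_k = 5000L),
    donor = list(n_variants_step = 3L, substitution_widths = 2L,
                 n_input = 20000L, n_output = 20000L,
                 uncoupling_rate = 0.35, error_rate = 0.001,
                 abundance_sdlog = 0.5),
    coupling = list(n_pairs = 10000L),
    target = list(n_input = 30000L, n_output = 30000L, target = "A"),
    tn7 = list(n_reads = 5000L,
               class_probs = c(unintegrated = 0.7, "d00_T-RL" = 0.25,
                               "d02_T-LR" = 0.05))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()] entries;
#' schema violations are reported with the offending key.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (cfg$distance_window[1] > cfg$distance_window[2]) {
    stop("config error: distance_window lower bound exceeds upper bound",
         call. = FALSE)
  }
  if (cfg$logo$threshold <= 0) {
    stop("config error: logo$threshold must be > 0", call. = FALSE)
  }
  cfg
}

config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2L)
  unname(tools::md5sum(f))
}

provenance_lines <- function(config) {
  c(sprintf("castscreen %s",
            as.character(utils::packageVersion("castscreen"))),
    sprintf("seed=%d", config$seed),
    sprintf("config_md5=%s", config_fingerprint(config)))
}

#' Run the demonstration pipeline
#'
#' Deterministic end-to-end run at demo scale: builds the wild-type
#' fixture, designs and barcodes a right-end variant library, simulates
#' donor input/output and coupling reads, quantifies enrichment and
#' coupling, simulates a degenerate target library, calls integration
#' sites, builds the TSD logo, fits the preference model and predicts
#' integration distances, recodes the minimal right end into linkers, and
#' classifies simulated Tn7 amplicons. All tables are written as TSV with
#' provenance headers; a JSON QC summary accompanies them.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of the produced file paths and key
#'   in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_lines(config)
  path <- function(f) file.path(out_dir, f)
  seed <- config$seed

  tn <- make_wt_fixture()
  write_fasta(c(left_end = tn$left_end$sequence,
                right_end = tn$right_end$sequence,
                mini_tn = mini_tn_sequence(tn)), path("fixture.fasta"))
  write_tsv_prov(end_annotation_table(tn$left_end),
                 path("left_end_annotation.tsv"), prov)

  variants <- rbind(
    design_truncations(tn$right_end, step = config$donor$n_variants_step),
    design_substitutions(tn$right_end,
                         widths = config$donor$substitution_widths))
  manifest <- assign_barcodes(variants, tn$right_end$sequence, seed = seed)
  write_manifest(manifest, path("manifest.tsv"), prov)

  truth <- sim_truth(manifest,
                     abundance_sdlog = config$donor$abundance_sdlog,
                     uncoupling_rate = config$donor$uncoupling_rate,
                     error_rate = config$donor$error_rate, seed = seed)
  write_truth(truth, path("truth.tsv"))
  sim <- simulate_donor_reads(manifest, truth, config$donor$n_input,
                              config$donor$n_output, cargo = tn$cargo,
                              seed = seed + 1L)
  input_ct <- count_barcodes(sim$input, manifest, "input")
  output_ct <- count_barcodes(sim$output, manifest, "output")
  enr <- enrichment(input_ct, output_ct, wt_ids(manifest))
  write_counts(input_ct, path("counts_input.tsv"), prov)
  write_counts(output_ct, path("counts_output.tsv"), prov)
  write_counts(enr, path("enrichment.tsv"), prov)

  pairs <- simulate_coupling_pairs(manifest, truth, config$coupling$n_pairs,
                                   seed = seed + 2L)
  coupling <- coupling_qc(pairs$read1, pairs$read2, manifest)
  write_tsv_prov(coupling$per_variant, path("coupling.tsv"), prov)

  model <- default_insertion_model()
  tsim <- simulate_target_reads(model, config$target$n_input,
                                config$target$n_output,
                                target = config$target$target,
                                ends = list(left = tn$left_end$sequence,
                                            right = tn$right_end$sequence),
                                seed = seed + 3L)
  region <- target_region(config$target$target)
  calls <- call_integration(tsim$output$i5, tsim$output$i7, region,
                            ends = list(left = tn$left_end$sequence,
                                        right = tn$right_end$sequence))
  write_tsv_prov(calls[calls$called, , drop = FALSE], path("calls.tsv"), prov)
  denr <- degenerate_enrichment(input_degenerate_mers(tsim$input, region),
                                calls)
  write_counts(denr, path("degenerate_enrichment.tsv"), prov)
  logo <- build_logo(denr, threshold = config$logo$threshold,
                     top_k = config$logo$top_k)
  logo_df <- data.frame(position = colnames(logo), t(unclass(logo)),
                        ic = attr(logo, "ic"))
  write_tsv_prov(logo_df, path("tsd_logo.tsv"), prov)
  fitted <- fit_preference_model(denr, threshold = config$logo$threshold,
                                 top_k = config$logo$top_k)
  demo_seq <- gsub("N", "A", region$downstream)
  pred <- predict_sites(fitted, demo_seq)
  write_tsv_prov(as.data.frame(pred), path("site_prediction.tsv"), prov)

  min_end <- make_wt_fixture(minimal_right = TRUE)$right_end
  linkers <- lapply(1:3, function(f) {
    design_linkers(min_end$sequence, frame = f,
                   immutable_mask = conserved_tbs_mask(min_end),
                   max_variants = 2L)
  })
  linker_df <- do.call(rbind, lapply(unlist(linkers, recursive = FALSE),
    function(v) data.frame(name = v$name, frame = v$frame, dna = v$dna,
                           protein = v$protein, n_edits = nrow(v$edits))))
  write_tsv_prov(linker_df, path("linkers.tsv"), prov)

  tn7_prefixes <- tn7_class_prefixes(list(left = tn$left_end$sequence,
                                          right = tn$right_end$sequence))
  tn7_reads <- simulate_tn7_reads(config$tn7$n_reads, config$tn7$class_probs,
                                  tn7_prefixes, seed = seed + 4L)
  tn7_tab <- classify_tn7(tn7_reads, tn7_prefixes)
  write_tsv_prov(data.frame(class = names(tn7_tab$counts),
                            count = unname(tn7_tab$counts)),
                 path("tn7_classes.tsv"), prov)

  qc <- list(
    seed = seed,
    config_md5 = config_fingerprint(config),
    donor = list(n_input = input_ct$n_total_reads,
                 input_pass_filter = input_ct$n_pass_filter,
                 input_barcode_matched = input_ct$n_barcode_matched,
                 output_barcode_matched = output_ct$n_barcode_matched,
                 wt_mean_normalized =
                   mean(enr$normalized_score[enr$variant_id %in%
                                               wt_ids(manifest)])),
    coupling = list(overall_fraction_correct =
                      coupling$overall_fraction_correct,
                    mean_most_abundant_incorrect =
                      coupling$mean_most_abundant_incorrect),
    target = list(n_calls = sum(calls$called),
                  call_rate = mean(calls$called),
                  logo_selected = attr(logo, "n_selected"),
                  logo_shortfall = attr(logo, "shortfall"),
                  top_predicted_distance = pred$distance[1L]),
    tn7 = list(integrated_fraction = tn7_tab$integrated_fraction,
               unclassified = tn7_tab$n_unclassified))
  jsonlite::write_json(qc, path("qc_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(out_dir = out_dir, manifest = manifest, enrichment = enr,
                 coupling = coupling, calls = calls, logo = logo,
                 model = fitted, prediction = pred, tn7 = tn7_tab,
                 qc = qc))
}
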