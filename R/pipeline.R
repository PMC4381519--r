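#' Default pipeline configuration
#'
#' All analysis thresholds in one place, each defaulting to the published
#' value: minimum segment evidence (3 GCH sites), local background window
#' (±100 kb), FDR cutoff (0.01), NDR length rule (> 100 bp), promoter
#' window (−300/+500 bp), coverage filter (3 HCG sites / 10 reads),
#' methylation cutoffs (5%, 60%, 25%), autocorrelation range (0–700 bp) and
#' bin (10 bp), domain window (1 Mb) and the HMM chain-break gap (500 bp).
#' Simulation fields control the bundled synthetic data set.
#'
#' @param ... Overrides of any default; unknown keys are rejected.
#' @return A named list of class `nome_pipeline_config`.
#' @export
nome_pipeline_config <- function(...) {
  cfg <- list(
    # analysis thresholds
    min_sites = 3, flank = 100000, fdr = 0.01, ndr_min_len = 100,
    window_upstream = 300, window_downstream = 500,
    min_hcg_sites = 3, min_reads = 10,
    unmeth = 0.05, meth_a = 0.60, meth_b = 0.25,
    autocorr_max = 700, bin = 10, domain_window = 1e6, max_gap = 500,
    profile_flank = 1000,
    # simulation
    chrom_length = 1e6, n_ndr = 20, repeat_length = 190,
    mean_gch_spacing = 15, mean_hcg_spacing = 50,
    enzyme_efficiency = 0.8, background_leak = 0.05,
    mean_depth = 30, depth_dispersion = 0.1,
    domain_start = NA, domain_end = NA, domain_scale = NA,
    seed = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "nome_pipeline_config"
  cfg
}

.load_config <- function(config) {
  if (is.null(config)) return(nome_pipeline_config())
  if (inherits(config, "nome_pipeline_config")) return(config)
  if (is.character(config)) config <- yaml::read_yaml(config)
  do.call(nome_pipeline_config, config)
}

.config_md5 <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(outdir, stage, cfg, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package = as.character(utils::packageVersion("nomefoot")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_md5 = .config_md5(cfg),
    config = unclass(cfg),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

.sim_config_from <- function(cfg) {
  sim_config(mean_gch_spacing = cfg$mean_gch_spacing,
             mean_hcg_spacing = cfg$mean_hcg_spacing,
             enzyme_efficiency = cfg$enzyme_efficiency,
             background_leak = cfg$background_leak,
             mean_depth = cfg$mean_depth,
             depth_dispersion = cfg$depth_dispersion,
             seed = cfg$seed)
}

.read_segments_tsv <- function(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' Run the NOMe-seq analysis pipeline
#'
#' Orchestrates the stages of the accessibility analysis on one output
#' directory: `simulate` (bundled synthetic data set), `segment` (HMM
#' fitting and MAR/MPR decoding per sample replicate), `call-ndrs`
#' (significance testing and replicate intersection), `classify-promoters`,
#' `autocorr` (phasing statistic per promoter class), `profile`
#' (NDR-anchored accessibility matrix and metaplot), `domains` (1-Mb window
#' summaries), or `all`.  Each stage writes its declared artifacts plus a
#' JSON run manifest with the configuration hash and file checksums; reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param stage One of `"simulate"`, `"segment"`, `"call-ndrs"`,
#'   `"classify-promoters"`, `"autocorr"`, `"profile"`, `"domains"`,
#'   `"all"`.
#' @param config A [nome_pipeline_config()], a YAML path, a plain list of
#'   overrides, or `NULL` for all defaults.
#' @param outdir Output (and inter-stage input) directory.
#' @return Invisibly, the vector of artifact paths written.
#' @export
run_nome_pipeline <- function(stage = "all", config = NULL,
                              outdir = "nome_out") {
  stages <- c("simulate", "segment", "call-ndrs", "classify-promoters",
              "autocorr", "profile", "domains")
  if (!stage %in% c(stages, "all"))
    stop("unknown subcommand '", stage, "'; use one of: ",
         paste(c(stages, "all"), collapse = ", "))
  cfg <- .load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- unlist(lapply(stages, run_nome_pipeline, config = cfg,
                         outdir = outdir))
    return(invisible(out))
  }
  p <- function(...) file.path(outdir, paste0(...))
  message("[nomefoot] stage: ", stage)
  inputs <- character(0)
  outputs <- character(0)

  if (stage == "simulate") {
    domains <- if (!is.na(cfg$domain_start))
      data.frame(start = cfg$domain_start, end = cfg$domain_end,
                 scale = cfg$domain_scale) else NULL
    sim <- simulate_nome_experiment(
      chrom_length = cfg$chrom_length, n_ndr = cfg$n_ndr,
      domains = domains, repeat_length = cfg$repeat_length,
      config = .sim_config_from(cfg))
    for (s in c("a", "b")) for (r in 1:2) {
      f <- p("gch_", s, "_rep", r, ".tsv")
      write_cytosine_report(sim[[paste0("gch_", s)]][[r]], f)
      outputs <- c(outputs, f)
    }
    write_cytosine_report(sim$hcg_a, p("hcg_a.tsv"))
    write_cytosine_report(sim$hcg_b, p("hcg_b.tsv"))
    write_bed(sim$tss, p("tss.bed"))
    write_bed(sim$cgi, p("cgi.bed"))
    truth <- sim$truth_ndrs_b
    truth$name <- "NDR"
    write_bed(truth, p("truth_ndrs_b.bed"))
    write.table(sim$truths, p("promoter_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(cfg), p("config.yaml"))
    outputs <- c(outputs, p("hcg_a.tsv"), p("hcg_b.tsv"), p("tss.bed"),
                 p("cgi.bed"), p("truth_ndrs_b.bed"),
                 p("promoter_truth.tsv"), p("config.yaml"))
  }

  if (stage == "segment") {
    for (s in c("a", "b")) for (r in 1:2) {
      f <- p("gch_", s, "_rep", r, ".tsv")
      inputs <- c(inputs, f)
      calls <- read_cytosine_report(f, context_filter = "GCH")
      fit <- fit_nome_hmm(calls, max_gap = cfg$max_gap)
      segs <- segment_calls(fit, calls, min_sites = cfg$min_sites)
      tsv <- p("segments_", s, "_rep", r, ".tsv")
      write.table(segs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      bed <- p("segments_", s, "_rep", r, ".bed")
      write_segments_bed(segs, bed)
      par_f <- p("hmm_params_", s, "_rep", r, ".yaml")
      cf <- coef(fit)
      yaml::write_yaml(list(
        emission = apply(cf$emission, 1, as.list, simplify = FALSE),
        mean = as.list(cf$mean), dispersion = as.list(cf$dispersion),
        transition = apply(cf$transition, 1, as.list, simplify = FALSE),
        initial = as.list(cf$initial),
        loglik = fit$loglik[length(fit$loglik)],
        converged = fit$converged, max_gap = fit$max_gap), par_f)
      outputs <- c(outputs, tsv, bed, par_f)
    }
  }

  if (stage == "call-ndrs") {
    for (s in c("a", "b")) {
      reps <- list()
      for (r in 1:2) {
        f <- p("segments_", s, "_rep", r, ".tsv")
        inputs <- c(inputs, f)
        segs <- .read_segments_tsv(f)
        ndr <- call_ndrs(segs, flank = cfg$flank, fdr = cfg$fdr,
                         min_len = cfg$ndr_min_len)
        tsv <- p("ndr_", s, "_rep", r, ".tsv")
        write.table(ndr, tsv, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <- c(outputs, tsv)
        reps[[r]] <- ndr
      }
      supported <- intersect_replicates(reps[[1]], reps[[2]])
      f <- p("ndrs_", s, ".tsv")
      write.table(supported, f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      message("[nomefoot] sample ", s, ": ",
              sum(reps[[1]]$is_ndr), " / ", sum(reps[[2]]$is_ndr),
              " NDRs per replicate, ", nrow(supported),
              " replicate-supported")
      outputs <- c(outputs, f)
    }
  }

  if (stage == "classify-promoters") {
    inputs <- c(p("hcg_a.tsv"), p("hcg_b.tsv"), p("tss.bed"),
                p("cgi.bed"), p("ndrs_b.tsv"),
                p("gch_b_rep1.tsv"), p("gch_b_rep2.tsv"))
    hcg_a <- read_cytosine_report(p("hcg_a.tsv"))
    hcg_b <- read_cytosine_report(p("hcg_b.tsv"))
    tss <- read_bed(p("tss.bed"))
    cgi <- read_bed(p("cgi.bed"))
    ndrs <- .read_segments_tsv(p("ndrs_b.tsv"))
    # promoter analyses combine the replicates of each sample
    gch_b <- rbind(read_cytosine_report(p("gch_b_rep1.tsv")),
                   read_cytosine_report(p("gch_b_rep2.tsv")))
    prom <- data.frame(gene = tss$name, chrom = tss$chrom,
                       start = tss$start, tss = tss$start,
                       strand = tss$strand, stringsAsFactors = FALSE)
    iv <- .halfopen_to_iranges(tss$start, tss$end)
    civ <- .halfopen_to_iranges(cgi$start, cgi$end)
    prom$is_cgi <- IRanges::countOverlaps(iv, civ) > 0
    tab <- promoter_chromatin_table(
      prom[, c("gene", "chrom", "tss", "strand", "is_cgi")],
      hcg_a, hcg_b, gch_b = gch_b, ndrs = ndrs,
      min_sites = cfg$min_hcg_sites, min_reads = cfg$min_reads,
      unmeth = cfg$unmeth, meth_a = cfg$meth_a, meth_b = cfg$meth_b)
    f <- p("promoters.tsv")
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    cnt <- table(tab$class_label)
    message("[nomefoot] promoter classes: ",
            paste(names(cnt), cnt, sep = "=", collapse = ", "))
    outputs <- c(outputs, f)
  }

  if (stage == "autocorr") {
    inputs <- c(p("promoters.tsv"), p("gch_a_rep1.tsv"),
                p("gch_a_rep2.tsv"), p("gch_b_rep1.tsv"),
                p("gch_b_rep2.tsv"))
    tab <- .read_segments_tsv(p("promoters.tsv"))
    gch <- list(
      a = rbind(read_cytosine_report(p("gch_a_rep1.tsv")),
                read_cytosine_report(p("gch_a_rep2.tsv"))),
      b = rbind(read_cytosine_report(p("gch_b_rep1.tsv")),
                read_cytosine_report(p("gch_b_rep2.tsv"))))
    for (cl in intersect(c("UU", "MU", "MM"), unique(tab$class_label))) {
      sel <- tab[tab$class_label == cl, , drop = FALSE]
      if (nrow(sel) < 2) next
      for (s in c("a", "b")) {
        ac <- phasing_autocorrelation(gch[[s]], sel,
                                      max_dist = cfg$autocorr_max,
                                      bin = cfg$bin)
        f <- p("autocorr_", cl, "_", s, ".tsv")
        write.table(ac, f, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, f)
      }
    }
  }

  if (stage == "profile") {
    inputs <- c(p("ndrs_b.tsv"), p("gch_b_rep1.tsv"), p("gch_b_rep2.tsv"))
    ndrs <- .read_segments_tsv(p("ndrs_b.tsv"))
    gch_b <- rbind(read_cytosine_report(p("gch_b_rep1.tsv")),
                   read_cytosine_report(p("gch_b_rep2.tsv")))
    anchors <- data.frame(chrom = ndrs$chrom,
                          pos = (ndrs$start + ndrs$end) %/% 2,
                          strand = "+")
    prof <- aggregate_profile(gch_b, anchors, flank = cfg$profile_flank,
                              bin = cfg$bin)
    mat <- as.data.frame(prof$matrix)
    names(mat) <- paste0("bp_", prof$offsets)
    f1 <- p("profile_ndr_b.tsv")
    write.table(cbind(anchors, mat), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f2 <- p("metaplot_ndr_b.tsv")
    write.table(data.frame(offset = prof$offsets, level = prof$metaplot),
                f2, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f1, f2)
  }

  if (stage == "domains") {
    inputs <- c(p("gch_b_rep1.tsv"), p("gch_b_rep2.tsv"), p("hcg_b.tsv"),
                p("cgi.bed"), p("config.yaml"))
    gch_b <- rbind(read_cytosine_report(p("gch_b_rep1.tsv")),
                   read_cytosine_report(p("gch_b_rep2.tsv")))
    hcg_b <- read_cytosine_report(p("hcg_b.tsv"))
    cgi <- read_bed(p("cgi.bed"))
    lens <- setNames(cfg$chrom_length, unique(gch_b$chrom)[1])
    ws <- window_summarize(gch_b, hcg_b, tracks = list(),
                           chrom_lengths = lens,
                           window = cfg$domain_window, cgi = cgi)
    f <- p("domains.tsv")
    write.table(ws, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  outputs <- c(outputs, .write_manifest(outdir, stage, cfg, inputs,
                                        outputs))
  invisible(outputs)
}
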