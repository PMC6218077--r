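#' Read a flat key/value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are kept as
#' strings except for the recognised numeric settings.
#'
#' @param path Configuration file.
#' @return Named list of class `rh1_run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- setNames(lapply(kv, function(x) paste(x[-1], collapse = " = ")),
                  vapply(kv, `[[`, "", 1))
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of settings; see Details.
#' @details Recognised keys: `alignment`, `species_tree`, `lineage_map`
#'   (optional TSV taxon/tag), `character_matrix`, `backbone_tree`,
#'   `keysite_pairs` (optional TSV taxon_a/taxon_b), `out_dir`, `seed`,
#'   `frame_offset`, `ry3` (recode third positions), `n_starts`, `boot`,
#'   `au_B`, `alpha`, `optimize_model`, `gamma_shape`, `site_weight` etc.
#'   Numeric defaults follow the study settings (5 search starts, 1000
#'   bootstrap replicates, AU scales 0.5-1.4, alpha 0.05).
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(
    alignment = NULL, species_tree = NULL, lineage_map = NULL,
    character_matrix = NULL, backbone_tree = NULL, keysite_pairs = NULL,
    out_dir = "rhodup_run", seed = 1L, frame_offset = 0L, ry3 = TRUE,
    n_starts = 5L, boot = 1000L, au_B = 1000L, alpha = 0.05,
    optimize_model = TRUE, gamma_shape = 0.5)
  cfg <- utils::modifyList(defaults, cfg)
  for (k in c("seed", "frame_offset", "n_starts", "boot", "au_B")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in c("alpha", "gamma_shape")) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in c("ry3", "optimize_model")) {
    cfg[[k]] <- as.logical(cfg[[k]]) %||% TRUE
  }
  structure(cfg, class = "rh1_run_config")
}

pipeline_stage <- function(name, expr, manifest) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    rec <- list(stage = name, error = conditionMessage(e))
    jsonlite::write_json(rec, file.path(manifest$out_dir, "error.json"),
                         auto_unbox = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  list(res = res, manifest = manifest)
}

#' Run the full analysis chain from a configuration
#'
#' Composition report and RY-recoding, ML tree with bootstrap supports,
#' hypothesis evaluation (constrained searches + AU test), parsimony
#' ancestral-state reconstruction, and key-site comparison, writing all
#' outputs plus a run manifest into the configured output directory.
#' Any stage failure aborts with the stage name and leaves a machine-readable
#' `error.json`.
#'
#' @param config An `rh1_run_config` (see [run_config()]).
#' @return Named list of stage results, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "rh1_run_config")) config else run_config(config)
  if (is.null(cfg$alignment)) stop("config needs an alignment path")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(out_dir = cfg$out_dir, seed = cfg$seed,
                   package = as.character(packageVersion("rhodup")),
                   r_version = R.version.string, timings = list())
  results <- list()

  st <- pipeline_stage("prep", {
    aln <- read_fasta_alignment(cfg$alignment, frame_offset = cfg$frame_offset)
    comp <- do.call(rbind, lapply(1:3, function(p) {
      ct <- composition_homogeneity_test(aln, p)
      data.frame(codon_position = p, chi2 = ct$statistic, df = ct$df,
                 p_value = ct$p_value)
    }))
    write.table(comp, file.path(cfg$out_dir, "composition_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    used <- if (isTRUE(cfg$ry3)) ry_recode(aln, 3L) else aln
    write_fasta_alignment(used, file.path(cfg$out_dir, "alignment_used.fasta"))
    list(aln = aln, used = used, comp = comp)
  }, manifest)
  manifest <- st$manifest
  results$prep <- st$res
  used <- results$prep$used

  model0 <- substitution_model(base_freqs = empirical_base_freqs(used),
                               gamma_shape = cfg$gamma_shape)

  st <- pipeline_stage("ml", {
    fit <- ml_search(used, model0, n_starts = cfg$n_starts, seed = cfg$seed,
                     optimize_model = cfg$optimize_model)
    btree <- bootstrap_support(used, fit$model, B = cfg$boot,
                               seed = derive_seed(cfg$seed, 77L),
                               tree = fit$tree)
    ape::write.tree(btree, file.path(cfg$out_dir, "best_tree.nwk"))
    list(fit = fit, tree = btree)
  }, manifest)
  manifest <- st$manifest
  results$ml <- st$res

  st <- pipeline_stage("hyptest", {
    lmap <- NULL
    if (!is.null(cfg$lineage_map)) {
      lmap <- read.delim(cfg$lineage_map, colClasses = "character")
    }
    ev <- evaluate_hypotheses(used, model0, lineage_map = lmap,
                              n_starts = 1L, seed = cfg$seed,
                              optimize_model = cfg$optimize_model,
                              au_B = cfg$au_B, alpha = cfg$alpha)
    write.table(ev$report, file.path(cfg$out_dir, "hypothesis_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_sitelik_matrix(ev$sitelik, file.path(cfg$out_dir, "sitelik.tsv"))
    ev
  }, manifest)
  manifest <- st$manifest
  results$hyptest <- st$res

  if (!is.null(cfg$character_matrix)) {
    st <- pipeline_stage("acr", {
      chars <- read.delim(cfg$character_matrix, colClasses = "character")
      rownames(chars) <- chars$taxon
      chars <- chars[, setdiff(colnames(chars), "taxon"), drop = FALSE]
      btree <- if (!is.null(cfg$backbone_tree)) {
        ape::read.tree(cfg$backbone_tree)
      } else {
        jawed_vertebrate_tree()
      }
      rows <- lapply(colnames(chars), function(ch) {
        acr <- fitch_acr(btree, setNames(chars[[ch]], rownames(chars)))
        data.frame(character = ch, min_changes = acr$min_changes,
                   states = paste(acr$universe, collapse = "/"))
      })
      rep <- do.call(rbind, rows)
      if ("intronless_rh1_copies" %in% colnames(chars)) {
        teleo <- intersect(teleost_taxa(), rownames(chars))
        rep$teleost_1to2_gains <- NA_integer_
        rep$teleost_1to2_gains[rep$character == "intronless_rh1_copies"] <-
          count_gains(btree,
                      setNames(chars$intronless_rh1_copies, rownames(chars)),
                      "1", "2", clade = teleo)
      }
      write.table(rep, file.path(cfg$out_dir, "acr_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    }, manifest)
    manifest <- st$manifest
    results$acr <- st$res
  }

  if (!is.null(cfg$keysite_pairs)) {
    st <- pipeline_stage("keysites", {
      pairs <- read.delim(cfg$keysite_pairs, colClasses = "character")
      prot <- translate_cds(results$prep$aln)
      out <- NULL
      for (i in seq_len(nrow(pairs))) {
        cmp <- compare_paralog_key_sites(prot[[pairs$taxon_a[i]]],
                                         prot[[pairs$taxon_b[i]]])
        cmp$taxon_a <- pairs$taxon_a[i]
        cmp$taxon_b <- pairs$taxon_b[i]
        out <- rbind(out, cmp)
      }
      write.table(out, file.path(cfg$out_dir, "keysites.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out
    }, manifest)
    manifest <- st$manifest
    results$keysites <- st$res
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(results)
}

#' Run the whole chain on a packaged synthetic demonstration
#'
#' Simulates a gene family under scenario B6 (the study's best-supported
#' hypothesis) on the compact species tree, writes the inputs, and runs
#' [run_pipeline()] on them with desk-scale settings.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param site_count Alignment length.
#' @param boot,au_B Bootstrap / AU replicate counts (reduced for a fast
#'   demonstration; raise towards 1000 for real use).
#' @param optimize_model Re-optimise model parameters per tree.
#' @return The [run_pipeline()] results, invisibly.
#' @export
demo_pipeline <- function(out_dir, seed = 1L, site_count = 996L,
                          boot = 30L, au_B = 200L, optimize_model = TRUE) {
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  truth <- simulate_gene_tree(rh1_species_tree(), "B6", seed = seed)
  aln <- simulate_alignment(truth, simulation_model(site_count = site_count),
                            seed = seed)
  write_gene_family(truth, aln, file.path(out_dir, "inputs"))
  write.table(truth$leaf_map[, c("leaf", "tag")],
              file.path(out_dir, "inputs", "lineage_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("taxon", "tag"))
  pairs <- data.frame(taxon_a = "Elops__Elops_dso",
                      taxon_b = "Elops__Elops_fwo")
  write.table(pairs, file.path(out_dir, "inputs", "keysite_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run_config(list(
    alignment = file.path(out_dir, "inputs", "alignment.fasta"),
    species_tree = file.path(out_dir, "inputs", "species_tree.nwk"),
    lineage_map = file.path(out_dir, "inputs", "lineage_map.tsv"),
    character_matrix = system.file("extdata", "opsin_characters.tsv",
                                   package = "rhodup"),
    keysite_pairs = file.path(out_dir, "inputs", "keysite_pairs.tsv"),
    out_dir = out_dir, seed = seed, n_starts = 1L, boot = boot,
    au_B = au_B, optimize_model = optimize_model))
  run_pipeline(cfg)
}
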