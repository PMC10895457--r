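# End-to-end orchestration from a single structured-text (YAML) config,
# plus a bundled synthetic demo exercising every stage.
#
# Config keys (all stage parameters default to the standard protocol
# values: block 40, 5 shades, 6 A contact cutoff, 100 ns discard, 20 ns
# branch interval):
#   system:        label
#   topology:      PDB path
#   trajectories:  list of DCD / multi-model PDB paths
#   replica:       labels (optional), dt: ns per frame, stride
#   stages:        subset of [descriptors, cluster, df, dnemd, mlce]
#   df:            {block_size, levels, statistic}
#   cluster:       {align_resid, cluster_resid, k_min, k_max, linkage}
#   dnemd:         {pairs_manifest, snapshot_time, superpose_first}
#   mlce:          {energy, structure, cutoff, fraction, min_run}
#   output_dir, seed

#' Run the full analysis pipeline from a config
#'
#' Executes the enabled stages in dependency order and writes TSV/PDB/JSON
#' outputs plus a manifest with an md5 hash of every produced file.
#' Re-running with an identical config and inputs reproduces the numeric
#' outputs byte-identically.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  stopifnot(!is.null(cfg$topology), !is.null(cfg$output_dir))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(unlist(p), function(x)
      if (grepl("^(/|[A-Za-z]:)", x)) x else file.path(base_dir, x), "",
      USE.NAMES = FALSE)
  }
  cfg$topology <- rel(cfg$topology)
  cfg$trajectories <- rel(cfg$trajectories)
  cfg$dnemd$pairs_manifest <- rel(cfg$dnemd$pairs_manifest)
  cfg$mlce$energy <- rel(cfg$mlce$energy)
  cfg$mlce$structure <- rel(cfg$mlce$structure)
  if (!grepl("^/", cfg$output_dir)) cfg$output_dir <-
    file.path(base_dir, cfg$output_dir)
  stages <- cfg$stages %||% c("descriptors", "df")
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  topo <- read_structure(cfg$topology)
  ens <- NULL
  if (!is.null(cfg$trajectories)) {
    ens <- read_ensemble(topo, unlist(cfg$trajectories),
                         replica = unlist(cfg$replica %||% NULL),
                         stride = cfg$stride %||% 1L,
                         dt = cfg$dt %||% 1)
  }
  produced <- character(0)
  warnings_log <- character(0)
  emit <- function(path) produced <<- c(produced, path)

  if ("descriptors" %in% stages) {
    stopifnot(!is.null(ens))
    ca <- select_atoms(topo, "calpha")
    rs <- rmsd_series(ens, ca, ca, reference = topo)
    p <- file.path(out, "rmsd.tsv")
    utils::write.table(
      data.frame(replica = rs$replica, time = rs$time,
                 rmsd = sprintf("%.6f", rs$values)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    rf <- rmsf_profile(ens, ca)
    lab <- residue_labels(topo)
    p <- file.path(out, "rmsf.tsv")
    utils::write.table(
      data.frame(chain = lab$chain, resid = lab$resid,
                 rmsf = sprintf("%.6f", rf)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    p <- file.path(out, "rmsf_bfactor.pdb")
    write_structure(topo, p, bfactor = rf)
    emit(p)
  }

  if ("cluster" %in% stages) {
    stopifnot(!is.null(ens), !is.null(cfg$cluster$align_resid),
              !is.null(cfg$cluster$cluster_resid))
    al <- select_atoms(topo, "resid", resid = cfg$cluster$align_resid,
                       label = "ordered")
    cl <- select_atoms(topo, "resid", resid = cfg$cluster$cluster_resid,
                       label = "disordered")
    kc <- seq(cfg$cluster$k_min %||% 2L, cfg$cluster$k_max %||% 10L)
    cm <- cluster_conformations(ens, al, cl, k_candidates = kc,
                                linkage = cfg$cluster$linkage %||% "average")
    p <- file.path(out, "clusters.tsv")
    utils::write.table(
      data.frame(frame = seq_along(cm$assignment), replica = ens$replica,
                 time = ens$time, cluster = cm$assignment),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    for (i in seq_along(cm$medoids)) {
      rep_struct <- topo
      rep_struct$xyz <- ens$coords[, , cm$medoids[i]]
      p <- file.path(out, sprintf("cluster_rep_%02d.pdb", i))
      write_structure(rep_struct, p)
      emit(p)
    }
  }

  df_obj <- NULL
  if ("df" %in% stages) {
    stopifnot(!is.null(ens))
    ca <- select_atoms(topo, "calpha")
    df_obj <- compute_df(ens, ca,
                         statistic = cfg$df$statistic %||% "variance")
    p <- file.path(out, "df.tsv")
    write_matrix_tsv(df_obj$values, df_obj$labels, p); emit(p)
    bl <- block_average(df_obj, cfg$df$block_size %||% 40L)
    q <- quantize_df(bl, cfg$df$levels %||% 5L)
    p <- file.path(out, "df_block.tsv")
    utils::write.table(
      data.frame(block = bl$block_labels,
                 format(bl$values, digits = 10, trim = TRUE)),
      p, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = c("block", bl$block_labels)); emit(p)
    p <- file.path(out, "df_block_quantized.tsv")
    utils::write.table(
      data.frame(block = q$block_labels, q$quantized),
      p, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = c("block", q$block_labels)); emit(p)
    prof <- df_profile(df_obj)
    p <- file.path(out, "df_profile.tsv")
    utils::write.table(
      data.frame(chain = df_obj$labels$chain, resid = df_obj$labels$resid,
                 mean_df = sprintf("%.6f", prof)),
      p, sep = "\t", quote = FALSE, row.names = FALSE); emit(p)
    p <- file.path(out, "df_profile_bfactor.pdb")
    write_structure(topo, p, bfactor = prof[residue_index(topo)[ca$inds]])
    emit(p)
  }

  if ("dnemd" %in% stages) {
    stopifnot(!is.null(cfg$dnemd$pairs_manifest))
    prs <- read_paired_runs(cfg$dnemd$pairs_manifest, topo)
    rp <- compute_response(prs,
      superpose_first = cfg$dnemd$superpose_first %||% TRUE)
    p <- file.path(out, "dnemd_response.tsv")
    write_response_tsv(rp, p); emit(p)
    st <- cfg$dnemd$snapshot_time %||% max(rp$times)
    snap <- response_snapshot(rp, st, structure = topo)
    p <- file.path(out, sprintf("dnemd_snapshot_t%g.pdb", snap$time))
    write_structure(topo, p, bfactor = attr(snap$structure, "bfactor"))
    emit(p)
  }

  if ("mlce" %in% stages) {
    stopifnot(!is.null(cfg$mlce$energy))
    em <- read_energy_matrix(cfg$mlce$energy)
    ms <- if (!is.null(cfg$mlce$structure))
      read_structure(cfg$mlce$structure) else topo
    res <- mlce(em, structure = ms,
                cutoff = cfg$mlce$cutoff %||% 6,
                k = cfg$mlce$k %||% "auto",
                fraction = cfg$mlce$fraction %||% 0.10,
                min_run = cfg$mlce$min_run %||% 3L)
    p <- file.path(out, "mlce_map.tsv")
    write_matrix_tsv(res$map, res$labels, p); emit(p)
    p <- file.path(out, "mlce_core_segments.tsv")
    write_segments_tsv(res$core, res$labels, p); emit(p)
    p <- file.path(out, "mlce_soft_segments.tsv")
    write_segments_tsv(res$soft, res$labels, p); emit(p)
  }

  manifest <- list(
    tool = paste0("allodyn ",
                  as.character(utils::packageVersion("allodyn"))),
    system = cfg$system %||% "unnamed",
    stages = stages,
    config = cfg,
    outputs = lapply(stats::setNames(produced, basename(produced)),
                     function(p) list(md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a D-NEMD pair manifest into a paired run set
#'
#' YAML layout: `times:` (relative grid, ns) and `pairs:` - a list of
#' `{unperturbed, perturbed, branch_time}` trajectory-file entries
#' (multi-model PDB or DCD, one frame per grid time, Calpha sites only).
#'
#' @param path YAML manifest.
#' @param topology `md_structure` of the sites.
#' @return a `paired_run_set` (without ground truth).
#' @export
read_paired_runs <- function(path, topology) {
  man <- yaml::read_yaml(path)
  stopifnot(!is.null(man$pairs), !is.null(man$times))
  base_dir <- dirname(path)
  locate <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  pairs <- lapply(man$pairs, function(pr) {
    eu <- read_ensemble(topology, locate(pr$unperturbed))
    ep <- read_ensemble(topology, locate(pr$perturbed))
    list(unperturbed = eu$coords, perturbed = ep$coords,
         branch_time = pr$branch_time %||% NA_real_)
  })
  base::structure(list(pairs = pairs, times = unlist(man$times),
                       truth = NULL, labels = residue_labels(topology),
                       targets = NULL, model = NULL),
                  class = "paired_run_set")
}

#' Generate the bundled synthetic demo fixture set
#'
#' Emits a toy two-domain 40-residue system under `dir`: equilibrium
#' ensembles in two "ligand states" that differ by a planted inter-domain
#' decoupling, a 10-pair D-NEMD set with a planted response on residue 5,
#' an energy matrix with a planted folding core and soft patch, and a
#' ready-to-run `config.yaml`. Byte-identical under the same seed.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return named list of the generated paths, invisibly.
#' @export
make_demo <- function(seed = 1L, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- 40L
  # two small distal sites carry the ligand-state-dependent coordination
  site1 <- 1:8; site2 <- 33:40
  ref <- helix_coords(n)
  intra <- rbind(springs_chain(n, k = 5),
                 springs_contact(ref, cutoff = 7, k = 3))
  inter <- expand.grid(i = site1, j = site2)
  inter$k <- 2
  coupled <- harmonic_model(ref, rbind(intra, inter), sigma = 0.5,
                            seed = seed)
  decoupled <- harmonic_model(ref, intra, sigma = 0.5, seed = seed + 1L)

  topo_path <- file.path(dir, "topology.pdb")
  write_structure(synthetic_structure(ref), topo_path)

  paths <- list(topology = topo_path)
  for (st in c("coupled", "decoupled")) {
    model <- if (st == "coupled") coupled else decoupled
    traj <- character(0)
    for (r in 1:4) {
      # 50 frames every 20 ns: each replica spans the 1-us production
      # layout (stamps 0..980), so the default branch schedule applies
      e <- sample_harmonic_ensemble(model, frames = 50L, replicas = 1L,
                                    seed = model$seed * 1000L + r, dt = 20)
      p <- file.path(dir, sprintf("%s_r%d.pdb", st, r))
      write_ensemble_pdb(e, p)
      traj <- c(traj, p)
    }
    paths[[st]] <- traj
  }

  # paired D-NEMD set with a planted 1 A x-displacement of residue 5
  prs <- make_paired_dnemd_set(coupled, targets = 5L,
                               displacement = function(t) c(1, 0, 0),
                               branch_times = seq(120, 300, by = 20),
                               run_length = 5, dt = 1,
                               seed = seed + 7L)
  pair_files <- list()
  for (i in seq_along(prs$pairs)) {
    pu <- file.path(dir, sprintf("pair%02d_unperturbed.pdb", i))
    pp <- file.path(dir, sprintf("pair%02d_perturbed.pdb", i))
    s <- synthetic_structure(coupled$ref)
    eu <- md_ensemble(s, prs$pairs[[i]]$unperturbed, time = prs$times)
    ep <- md_ensemble(s, prs$pairs[[i]]$perturbed, time = prs$times)
    write_ensemble_pdb(eu, pu)
    write_ensemble_pdb(ep, pp)
    pair_files[[i]] <- list(unperturbed = basename(pu),
                            perturbed = basename(pp),
                            branch_time = prs$pairs[[i]]$branch_time)
  }
  manifest_path <- file.path(dir, "pairs.yaml")
  yaml::write_yaml(list(times = prs$times, pairs = pair_files),
                   manifest_path)

  # planted energy matrix + compact structure for contacts
  em <- make_energy_matrix(n, core = 10:14, core_strength = 10,
                           soft = 30:33, background = 0.3,
                           seed = seed + 11L)
  energy_path <- file.path(dir, "energy_matrix.tsv")
  write_energy_matrix(em, energy_path)
  mlce_struct_path <- file.path(dir, "mlce_structure.pdb")
  write_structure(synthetic_structure(globule_coords(n, seed = seed + 13L)),
                  mlce_struct_path)

  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    seed = seed, n_residues = n,
    coupled_sites = list(site1 = range(site1), site2 = range(site2)),
    decoupled_block = "site1 x site2 residue pairs",
    dnemd_target = 5, dnemd_displacement_A = 1.0,
    planted_core = 10:14, planted_soft = 30:33),
    truth_path, auto_unbox = TRUE, pretty = TRUE)

  config <- list(
    system = "demo",
    topology = basename(topo_path),
    trajectories = as.list(basename(paths$coupled)),
    replica = as.list(paste0("r", 1:4)),
    dt = 20, stride = 1,
    stages = list("descriptors", "cluster", "df", "dnemd", "mlce"),
    seed = seed,
    cluster = list(align_resid = "1-20", cluster_resid = "21-40",
                   k_min = 2, k_max = 6),
    df = list(block_size = 10, levels = 5),
    dnemd = list(pairs_manifest = basename(manifest_path),
                 snapshot_time = 5),
    mlce = list(energy = basename(energy_path),
                structure = basename(mlce_struct_path),
                cutoff = 6, fraction = 0.15, min_run = 3),
    output_dir = "out")
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  paths$config <- config_path
  paths$pairs_manifest <- manifest_path
  paths$energy <- energy_path
  paths$ground_truth <- truth_path
  invisible(paths)
}
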