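#' Trait table of a segmentation report
#'
#' @param report a \linkS4class{SegmentationReport}.
#' @return data.frame with one row per typical leaf: leaf_id, s_mm2, c_mm,
#'   l_mm, w_mm, x11..x16.
#' @export
traitTable <- function(report) {
  stopifnot(is(report, "SegmentationReport"))
  leaves <- report@typicalLeaves
  if (length(leaves) == 0L) {
    out <- data.frame(leaf_id = integer(0))
    for (nm in c("s_mm2", "c_mm", "l_mm", "w_mm", .trait_names[5:10]))
      out[[nm]] <- numeric(0)
    return(out)
  }
  rows <- lapply(seq_along(leaves), function(k) {
    v <- leaves[[k]]@traits@values
    data.frame(leaf_id = k, s_mm2 = v[["s"]], c_mm = v[["c"]],
               l_mm = v[["l"]], w_mm = v[["w"]],
               x11 = v[["x11"]], x12 = v[["x12"]], x13 = v[["x13"]],
               x14 = v[["x14"]], x15 = v[["x15"]], x16 = v[["x16"]])
  })
  do.call(rbind, rows)
}

#' Run the full measurement pipeline on a plant mesh
#'
#' Reads the scene mesh, removes the table and everything within the buffer
#' (pot, soil), runs the multi-level region-growing segmentation with the
#' evolving shape models, and writes per-leaf meshes (\code{leaf_<k>.ply}),
#' the trait table (\code{traits.csv}, \code{traits.json}), the final shape
#' model (\code{model.json}), the run report (\code{report.json}) and a run
#' log (\code{run.log}) with per-level thresholds and cluster counts. The
#' input file is never modified; identical input and configuration produce
#' identical outputs.
#'
#' @param input path to a PLY/OBJ scene mesh, or a
#'   \linkS4class{TriangleMesh}.
#' @param outputDir directory for outputs (created if missing); NULL writes
#'   nothing.
#' @param preprocess a \linkS4class{PreprocessConfig}.
#' @param segmentation a \linkS4class{SegmentationConfig}.
#' @return invisibly, a list with \code{report}
#'   (\linkS4class{SegmentationReport}), \code{traits} (data.frame),
#'   \code{plantMesh} and \code{plane}.
#' @export
runPipeline <- function(input, outputDir = NULL,
                        preprocess = PreprocessConfig(),
                        segmentation = SegmentationConfig()) {
  mesh <- if (is(input, "TriangleMesh")) input else readMesh(input)
  plane <- detectTablePlane(mesh, preprocess)
  plant <- removeNonPlant(mesh, plane, preprocess)
  report <- multilevelSegment(plant, segmentation)
  tab <- traitTable(report)

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(report@typicalLeaves))
      writeMesh(report@typicalLeaves[[k]]@submesh,
                file.path(outputDir, sprintf("leaf_%d.ply", k)))
    utils::write.csv(tab, file.path(outputDir, "traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tab, file.path(outputDir, "traits.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(report@finalModel))
      writeShapeModel(report@finalModel, file.path(outputDir, "model.json"))
    jsonlite::write_json(
      list(levels_run = report@levelsRun,
           n_typical = length(report@typicalLeaves),
           n_rejected = length(report@rejected),
           sigma_smooth = report@surfaceStats@sigmaSmooth,
           rho_curv = report@surfaceStats@rhoCurv,
           level_log = report@levelLog),
      file.path(outputDir, "report.json"), auto_unbox = TRUE, digits = NA)
    log_lines <- c(
      sprintf("plant mesh: %d vertices, %d faces",
              nrow(plant@vertices), nrow(plant@faces)),
      sprintf("table plane: normal (%.4f, %.4f, %.4f), offset %.3f, %d inliers",
              plane@normal[1], plane@normal[2], plane@normal[3],
              plane@offset, plane@inlierCount),
      sprintf("sigma = %.4f deg, rho = %.6f",
              report@surfaceStats@sigmaSmooth, report@surfaceStats@rhoCurv),
      apply(report@levelLog, 1, function(r) {
        sprintf("level %d: m=%.2f eps_a=%.4f eps_b=%.6f clusters=%d accepted=%d residual=%d",
                as.integer(r[["level"]]), r[["multiplier"]], r[["eps_a"]],
                r[["eps_b"]], as.integer(r[["clusters"]]),
                as.integer(r[["accepted"]]),
                as.integer(r[["residual_vertices"]]))
      }),
      sprintf("typical leaves: %d", length(report@typicalLeaves)))
    writeLines(log_lines, file.path(outputDir, "run.log"))
  }
  invisible(list(report = report, traits = tab, plantMesh = plant,
                 plane = plane))
}

# ---------------------------------------------------------------------------
# command-line interface (inst/scripts/leafmorph is a thin Rscript wrapper)
# ---------------------------------------------------------------------------

.cli_opt <- function(args, name, default = NULL) {
  hit <- which(args == paste0("--", name))
  if (length(hit) == 0L) return(default)
  args[hit[1] + 1L]
}

.cli_usage <- function() {
  cat("usage: leafmorph <command> [options]\n",
      "commands:\n",
      "  simulate --out scene.ply --ledger ledger.json [--spec spec.yaml]\n",
      "           [--leaves N] [--occlusion none|little|medium|heavy]\n",
      "           [--newborn N] [--dropout F] [--resolution MM] [--seed N]\n",
      "  segment  --input plant.ply --out DIR [--epsilon-mm MM]\n",
      "           [--ransac-tol-mm MM] [--ransac-iters N] [--seed N]\n",
      "  traits   --input leaf.ply\n",
      "  evaluate --pred traits_auto.csv --ref traits_manual.csv [--out CSV]\n",
      "  run      --input scene.ply --out DIR [--seed N]\n", sep = "")
}

#' Command-line entry point
#'
#' Dispatches the \code{simulate}, \code{segment}, \code{traits},
#' \code{evaluate} and \code{run} subcommands used by the
#' \code{inst/scripts/leafmorph} wrapper script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { .cli_usage(); return(invisible(1L)) }
  cmd <- args[1]
  args <- args[-1]
  seed <- as.integer(.cli_opt(args, "seed", "1"))
  status <- 0L
  if (cmd == "simulate") {
    spec_path <- .cli_opt(args, "spec")
    spec <- if (!is.null(spec_path)) .scene_spec_from_yaml(spec_path, seed)
    else PlantSceneSpec(
      nLeaves = as.integer(.cli_opt(args, "leaves", "6")),
      occlusionLevel = .cli_opt(args, "occlusion", "none"),
      nNewborn = as.integer(.cli_opt(args, "newborn", "0")),
      dropoutFraction = as.numeric(.cli_opt(args, "dropout", "0")),
      meshResolutionMm = as.numeric(.cli_opt(args, "resolution", "1.5")),
      rngSeed = seed)
    scene <- generatePlantScene(spec)
    writeMesh(scene$mesh, .cli_opt(args, "out", "scene.ply"))
    ledger_path <- .cli_opt(args, "ledger")
    if (!is.null(ledger_path)) writeLedger(scene$ledger, ledger_path)
    cat(sprintf("scene: %d vertices, %d faces, %d leaves (%d typical)\n",
                nVertices(scene$mesh), nFaces(scene$mesh),
                scene$ledger$counts$n0, scene$ledger$counts$n1))
  } else if (cmd %in% c("segment", "run")) {
    pre <- PreprocessConfig(
      epsilonMm = as.numeric(.cli_opt(args, "epsilon-mm", "100")),
      ransacIterations = as.integer(.cli_opt(args, "ransac-iters", "1000")),
      ransacInlierTolMm = as.numeric(.cli_opt(args, "ransac-tol-mm", "2")),
      rngSeed = seed)
    cfg_path <- .cli_opt(args, "config")
    seg <- if (!is.null(cfg_path)) .segmentation_config_from_yaml(cfg_path)
           else SegmentationConfig()
    res <- runPipeline(.cli_opt(args, "input"),
                       outputDir = .cli_opt(args, "out", "leafmorph_out"),
                       preprocess = pre, segmentation = seg)
    cat(sprintf("typical leaves: %d (levels run: %d)\n",
                length(res$report@typicalLeaves), res$report@levelsRun))
    if (length(res$report@typicalLeaves) == 0L) status <- 2L
  } else if (cmd == "traits") {
    mesh <- readMesh(.cli_opt(args, "input"))
    tv <- traitVector(mesh)
    print(tv)
  } else if (cmd == "evaluate") {
    pred <- utils::read.csv(.cli_opt(args, "pred"))
    ref <- utils::read.csv(.cli_opt(args, "ref"))
    cols <- setdiff(intersect(colnames(pred), colnames(ref)), "leaf_id")
    acc <- traitAccuracy(pred, ref, columns = cols)
    out <- .cli_opt(args, "out")
    if (!is.null(out)) utils::write.csv(acc, out, row.names = FALSE)
    print(acc)
  } else {
    .cli_usage()
    status <- 1L
  }
  invisible(status)
}

.scene_spec_from_yaml <- function(path, seed) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for --spec", call. = FALSE)
  y <- yaml::read_yaml(path)
  take <- function(nm, d) if (!is.null(y[[nm]])) y[[nm]] else d
  PlantSceneSpec(
    nLeaves = take("n_leaves", 6L),
    leafSemiAxesMm = unlist(take("leaf_semi_axes_mm", c(32.5, 20.5))),
    leafSizeCv = take("leaf_size_cv", 0.015),
    leafBendDeg = take("leaf_bend_deg", 20),
    occlusionLevel = take("occlusion_level", "none"),
    nNewborn = take("n_newborn", 0L),
    newbornScale = take("newborn_scale", 0.15),
    dropoutFraction = take("dropout_fraction", 0),
    tableSizeMm = take("table_size_mm", 400),
    potHeightMm = take("pot_height_mm", 80),
    meshResolutionMm = take("mesh_resolution_mm", 1.5),
    vertexNoiseMm = take("vertex_noise_mm", 0.05),
    rngSeed = as.integer(take("rng_seed", seed)))
}

.segmentation_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for --config", call. = FALSE)
  y <- yaml::read_yaml(path)
  take <- function(nm, d) if (!is.null(y[[nm]])) y[[nm]] else d
  SegmentationConfig(
    nP = take("n_p", 30L),
    initMultiplier = take("init_multiplier", 1.5),
    multiplierStep = take("multiplier_step", 0.05),
    epsilonFloor = take("epsilon_floor", 1e-4),
    minClusterVertices = take("min_cluster_vertices", 50L),
    qEndpoint = take("q_endpoint", 0.05),
    kWidthSlices = take("k_width_slices", 20L))
}
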