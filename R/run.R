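# Single-structure and batch workflows and the command-line interface.
# Each successful structure yields a result bundle on disk: adjacency
# matrix, edge list, node list, node/edge/network metric tables, GraphML
# and a plain-text run log (parameters + conventions; no timestamps, so
# repeated runs are byte-identical).

.default_cutoff <- function(network) {
  if (toupper(network) == "CALPHA") 7.0 else 8.0
}

.build_network <- function(s, network, table, e_thresh, d_cutoff,
                           node_weight, weight_file, exclude_adjacent,
                           lr_sep) {
  switch(toupper(network),
         AACEN = build_aacen(s, table, e_thresh = e_thresh,
                             d_cutoff = d_cutoff,
                             exclude_adjacent = exclude_adjacent,
                             lr_sep = lr_sep),
         NACEN = build_nacen(s, table, e_thresh = e_thresh,
                             d_cutoff = d_cutoff,
                             weight_mode = node_weight,
                             weight_file = weight_file,
                             exclude_adjacent = exclude_adjacent,
                             lr_sep = lr_sep),
         EACEN = build_eacen(s, table, e_thresh = e_thresh,
                             d_cutoff = d_cutoff,
                             exclude_adjacent = exclude_adjacent,
                             lr_sep = lr_sep),
         CALPHA = build_calpha(s, d_cutoff = d_cutoff,
                               exclude_adjacent = exclude_adjacent,
                               lr_sep = lr_sep),
         stop("unknown network type: ", network))
}

.write_bundle <- function(net, report, out_dir, input_label) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    adjacency = file.path(out_dir, "adjacency.tsv"),
    edge_list = file.path(out_dir, "edge_list.tsv"),
    node_list = file.path(out_dir, "node_list.tsv"),
    node_metrics = file.path(out_dir, "node_metrics.tsv"),
    edge_metrics = file.path(out_dir, "edge_metrics.tsv"),
    network_metrics = file.path(out_dir, "network_metrics.tsv"),
    graphml = file.path(out_dir, "network.graphml"),
    run_log = file.path(out_dir, "run_log.txt"))
  export_network(net, paths$adjacency, "adjacency_tsv")
  export_network(net, paths$edge_list, "edgelist_tsv")
  export_network(net, paths$node_list, "nodelist_tsv")
  export_network(net, paths$graphml, "graphml")
  .write_tsv(report$node_table, paths$node_metrics)
  .write_tsv(report$edge_table, paths$edge_metrics)
  .write_tsv(report$network_row, paths$network_metrics)
  log <- c(
    paste0("input: ", input_label),
    paste0("network_type: ", net$model_type),
    paste0("parameters: ",
           paste(names(net$params), unlist(lapply(net$params, format)),
                 sep = "=", collapse = "; ")),
    if (!is.null(net$provenance)) paste0("energy_table: ", net$provenance),
    paste0("conventions: ",
           paste(names(report$conventions), report$conventions, sep = "=",
                 collapse = "; ")),
    net$log)
  writeLines(log, paths$run_log)
  paths
}

#' Run the full single-structure pipeline
#'
#' Parse -> assign secondary structure -> build one network model ->
#' compute all metric levels -> write a result bundle.
#'
#' @param input Path to a PDB file, raw PDB text, or a 4-character PDB code.
#' @param network `"AACEN"`, `"NACEN"`, `"EACEN"` or `"CALPHA"` (case
#'   insensitive).
#' @param out_dir Output directory; the bundle is written to
#'   `out_dir/<structure_id>/<network>/`.
#' @param e_thresh Contact-energy threshold (edge iff e_ij < e_thresh).
#' @param d_cutoff Distance cutoff in Angstrom; defaults to 8 for the energy
#'   networks and 7 for the C-alpha network.
#' @param node_weight NACEN node-weight mode (`"sas"`, `"mass"`,
#'   `"hydrophobicity"`, `"polarity"`) or a custom weight file path.
#' @param weight_file Custom weight file (alternative to passing a path in
#'   `node_weight`).
#' @param energy_table `"default"` or a path to an energy-table file.
#' @param lr_sep Long-range sequence-separation threshold.
#' @param exclude_adjacent Same-chain sequence-adjacency exclusion.
#' @param no_fetch Forbid downloading structures by PDB code.
#' @return Invisibly, a list with `structure`, `network`, `report`, `paths`.
#' @export
run_single <- function(input, network = "AACEN", out_dir = ".",
                       e_thresh = 0, d_cutoff = NULL,
                       node_weight = "polarity", weight_file = NULL,
                       energy_table = "default", lr_sep = 12,
                       exclude_adjacent = 2, no_fetch = FALSE) {
  stopifnot(length(input) == 1)
  network <- toupper(network)
  network <- match.arg(network, .aan_types)
  if (is.null(d_cutoff)) d_cutoff <- .default_cutoff(network)
  s <- parse_structure(input, fetch = !no_fetch)
  s <- assign_secondary_structure(s)
  table <- if (network == "CALPHA") NULL else load_energy_table(energy_table)
  net <- .build_network(s, network, table, e_thresh, d_cutoff, node_weight,
                        weight_file, exclude_adjacent, lr_sep)
  report <- metrics_report(net, lr_sep = lr_sep)
  bundle_dir <- file.path(out_dir, s$structure_id, network)
  label <- if (grepl("\n", input, fixed = TRUE)) "<inline PDB text>" else
    input
  paths <- .write_bundle(net, report, bundle_dir, label)
  invisible(list(structure = s, network = net, report = report,
                 paths = paths, dir = bundle_dir))
}

#' Run the batch pipeline over multiple structures
#'
#' Every (structure, network type) combination is processed independently:
#' failures are recorded in the summary table with their stage error message
#' and never abort the batch.
#'
#' @param inputs Character vector of PDB paths/codes (length >= 1).
#' @param networks One or more network types; each type's bundles go to its
#'   own subdirectory.
#' @inheritParams run_single
#' @return The batch summary data frame (one row per structure x network:
#'   `structure_id`, `network_type`, `n`, `m`, `L_net`, `density`,
#'   `diameter`, `status`), also written to `out_dir/summary.tsv`.
#' @export
run_batch <- function(inputs, networks = "CALPHA", out_dir = ".",
                      e_thresh = 0, d_cutoff = NULL,
                      node_weight = "polarity", weight_file = NULL,
                      energy_table = "default", lr_sep = 12,
                      exclude_adjacent = 2, no_fetch = FALSE) {
  stopifnot(length(inputs) >= 1)
  networks <- toupper(networks)
  stopifnot(all(networks %in% .aan_types))
  rows <- list()
  for (input in inputs) {
    label <- if (grepl("\n", input, fixed = TRUE)) "inline" else
      sub("\\.(pdb|ent)$", "", basename(input), ignore.case = TRUE)
    for (network in networks) {
      row <- data.frame(structure_id = label, network_type = network,
                        n = NA_integer_, m = NA_integer_, L_net = NA_real_,
                        density = NA_real_, diameter = NA_real_,
                        status = "ok", stringsAsFactors = FALSE)
      res <- tryCatch(
        run_single(input, network = network, out_dir = out_dir,
                   e_thresh = e_thresh, d_cutoff = d_cutoff,
                   node_weight = node_weight, weight_file = weight_file,
                   energy_table = energy_table, lr_sep = lr_sep,
                   exclude_adjacent = exclude_adjacent,
                   no_fetch = no_fetch),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$status <- paste0("error: ", conditionMessage(res))
      } else {
        nm <- res$report$network_row
        row$structure_id <- res$structure$structure_id
        row[, c("n", "m", "L_net", "density", "diameter")] <-
          nm[, c("n", "m", "L_net", "density", "diameter")]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  summary <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(summary, file.path(out_dir, "summary.tsv"))
  summary
}

# --- command-line interface -------------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: aanet <single|batch> [options] INPUT [INPUT ...]",
    "",
    "options:",
    "  --network TYPE        aacen|nacen|eacen|calpha (repeatable in batch;",
    "                        default aacen; calpha for nucleic inputs)",
    "  --energy-threshold X  edge iff e_ij < X (default 0)",
    "  --distance-cutoff X   Angstrom (default 8; 7 for calpha)",
    "  --node-weight MODE    sas|mass|hydrophobicity|polarity|FILE (nacen)",
    "  --lr-sep N            long-range separation (default 12)",
    "  --energy-table FILE   custom contact-energy table",
    "  --out DIR             output directory (default '.')",
    "  --no-fetch            never download structures by PDB code",
    sep = "\n")
}

#' Command-line entry point
#'
#' Implements the `single` and `batch` subcommands over [run_single()] and
#' [run_batch()]. Installed alongside the package as the executable script
#' `inst/cli/aanet`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   trailing arguments of the Rscript invocation).
#' @return Exit status 0, invisibly; errors raise conditions (the script
#'   wrapper converts them to a nonzero exit).
#' @export
aanet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat(.cli_usage(), "\n")
    return(invisible(0L))
  }
  mode <- args[1]
  if (!mode %in% c("single", "batch")) {
    stop("argument error: unknown subcommand '", mode, "'\n", .cli_usage())
  }
  args <- args[-1]
  opt <- list(network = character(), e_thresh = 0, d_cutoff = NULL,
              node_weight = "polarity", lr_sep = 12,
              energy_table = "default", out = ".", no_fetch = FALSE)
  inputs <- character()
  i <- 1
  need <- function(i) {
    if (i + 1 > length(args)) {
      stop("argument error: ", args[i], " requires a value")
    }
    args[i + 1]
  }
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--network") {
      opt$network <- c(opt$network, strsplit(need(i), ",")[[1]])
      i <- i + 2
    } else if (a == "--energy-threshold") {
      opt$e_thresh <- as.numeric(need(i)); i <- i + 2
    } else if (a == "--distance-cutoff") {
      opt$d_cutoff <- as.numeric(need(i)); i <- i + 2
    } else if (a == "--node-weight") {
      opt$node_weight <- need(i); i <- i + 2
    } else if (a == "--lr-sep") {
      opt$lr_sep <- as.integer(need(i)); i <- i + 2
    } else if (a == "--energy-table") {
      opt$energy_table <- need(i); i <- i + 2
    } else if (a == "--out") {
      opt$out <- need(i); i <- i + 2
    } else if (a == "--no-fetch") {
      opt$no_fetch <- TRUE; i <- i + 1
    } else if (startsWith(a, "--")) {
      stop("argument error: unknown option '", a, "'")
    } else {
      inputs <- c(inputs, a); i <- i + 1
    }
  }
  if (length(opt$network) == 0) opt$network <- "aacen"
  if (any(is.na(opt$e_thresh)) || (!is.null(opt$d_cutoff) &&
                                   any(is.na(opt$d_cutoff)))) {
    stop("argument error: non-numeric threshold/cutoff")
  }
  if (length(inputs) == 0) stop("argument error: no input structures given")
  if (mode == "single") {
    if (length(inputs) != 1) {
      stop("argument error: 'single' takes exactly one input")
    }
    if (length(opt$network) != 1) {
      stop("argument error: 'single' takes exactly one --network")
    }
    res <- run_single(inputs, network = opt$network, out_dir = opt$out,
                      e_thresh = opt$e_thresh, d_cutoff = opt$d_cutoff,
                      node_weight = opt$node_weight,
                      energy_table = opt$energy_table, lr_sep = opt$lr_sep,
                      no_fetch = opt$no_fetch)
    nm <- res$report$network_row
    cat(sprintf("%s %s: n=%d m=%d L_net=%s density=%s diameter=%s\n",
                res$structure$structure_id, res$network$model_type,
                nm$n, nm$m, format(nm$L_net, digits = 6),
                format(nm$density, digits = 6),
                format(nm$diameter, digits = 6)))
    cat("results in:", res$dir, "\n")
  } else {
    summary <- run_batch(inputs, networks = opt$network, out_dir = opt$out,
                         e_thresh = opt$e_thresh, d_cutoff = opt$d_cutoff,
                         node_weight = opt$node_weight,
                         energy_table = opt$energy_table,
                         lr_sep = opt$lr_sep, no_fetch = opt$no_fetch)
    utils::write.table(summary, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (any(summary$status != "ok")) {
      warning(sum(summary$status != "ok"), " structure/network run(s) failed")
    }
  }
  invisible(0L)
}
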