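# Run configuration and manifests.
#
# Configs are flat key-value documents validated against a strict
# per-command schema: unknown keys are rejected, every seed is explicit,
# defaults are filled in so each persisted run record is self-contained.
# A manifest (JSON) snapshots the config, tool version and md5 checksums
# of inputs/outputs; re-running a manifest reproduces deterministic
# outputs bitwise.

# field spec: list(type = chr|int|num|flag, default = ... or NULL=required)
cli_schemas <- function() {
  req <- function(type) list(type = type, default = NULL)
  opt <- function(type, default) list(type = type, default = default)
  list(
    parse = list(pdb = req("chr"), chain = req("chr"),
                 model = opt("int", 1L), out_fasta = req("chr")),
    align = list(fasta = req("chr"), pdb = req("chr"), chain = req("chr"),
                 mode = opt("chr", "fragment"), match = opt("num", 1),
                 mismatch = opt("num", -1), gap = opt("num", -2),
                 out = req("chr")),
    graph = list(pdb = req("chr"), chain = opt("chr", ""),
                 scheme = opt("chr", "knn"), k = opt("int", 10L),
                 cutoff = opt("num", 8.0), symmetrize = opt("flag", FALSE),
                 out = req("chr")),
    embed = list(fasta = req("chr"), provider = opt("chr", "mock"),
                 width = opt("int", 1280L), seed = opt("int", 0L),
                 out = req("chr")),
    featurize = list(pdb = req("chr"), chain = req("chr"),
                     emb = req("chr"), mode = opt("chr", "replace"),
                     fasta = opt("chr", ""),
                     reconcile = opt("chr", "align"),
                     out = req("chr")),
    train = list(task = req("chr"), scheme = opt("chr", "knn"),
                 features = opt("chr", "structure_only"),
                 n_chains = opt("int", 300L), epochs = opt("int", 150L),
                 seed = opt("int", 1L), report = req("chr")),
    toy = list(task = req("chr"), scheme = opt("chr", "knn"),
               features = opt("chr", "structure_only"),
               runs = opt("int", 3L), n_chains = opt("int", 300L),
               epochs = opt("int", 150L), seed = opt("int", 1L),
               out = req("chr")),
    `eval-mqa` = list(table = req("chr"), out = req("chr")),
    `eval-dock` = list(true_pdb = req("chr"), pred_pdb = req("chr"),
                       receptor_chains = req("chr"),
                       ligand_chains = req("chr"),
                       convention = opt("chr", "fixed_receptor"),
                       cutoff = opt("num", 8.0), out = req("chr"))
  )
}

#' Validate a run configuration
#'
#' Checks a flat key-value config for one subcommand against its schema:
#' unknown keys are rejected by name, required keys enforced, defaults
#' filled, values coerced to their declared types.
#'
#' @param command subcommand name (see \code{\link{plmgraph_main}}).
#' @param args named list of raw values (typically strings from the
#'   command line).
#' @return class \code{run_config}: validated named list with
#'   \code{command} attribute.
#' @export
run_config <- function(command, args = list()) {
  schemas <- cli_schemas()
  if (!command %in% names(schemas))
    stopf("unknown command '%s' (expected one of: %s)", command,
          paste(names(schemas), collapse = ", "))
  schema <- schemas[[command]]
  unknown <- setdiff(names(args), names(schema))
  if (length(unknown) > 0L)
    stopf("unknown config key '%s' for command '%s'", unknown[1], command)
  cfg <- list()
  for (key in names(schema)) {
    f <- schema[[key]]
    if (!key %in% names(args)) {
      if (is.null(f$default))
        stopf("missing required config key '%s' for command '%s'",
              key, command)
      cfg[[key]] <- f$default
    } else {
      v <- args[[key]]
      cfg[[key]] <- switch(f$type,
        chr = as.character(v),
        int = {
          iv <- suppressWarnings(as.integer(v))
          if (is.na(iv)) stopf("config key '%s' must be an integer", key)
          iv
        },
        num = {
          nv <- suppressWarnings(as.numeric(v))
          if (is.na(nv)) stopf("config key '%s' must be numeric", key)
          nv
        },
        flag = tolower(as.character(v)) %in% c("true", "1", "yes"))
    }
  }
  structure(cfg, command = command, class = "run_config")
}

#' Write a run manifest
#'
#' @param path manifest path (JSON).
#' @param config a \code{run_config}.
#' @param argv the raw argument vector of the run.
#' @param inputs,outputs file paths to checksum (md5).
#' @return the manifest (invisibly), as written.
#' @export
write_manifest <- function(path, config, argv, inputs = character(),
                           outputs = character()) {
  sums <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  man <- list(tool = "plmgraph",
              version = as.character(utils::packageVersion("plmgraph")),
              command = attr(config, "command"),
              config = unclass(config),
              argv = as.list(argv),
              input_md5 = sums(inputs),
              output_md5 = sums(outputs),
              wall_clock_utc = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Re-execute a run from its manifest
#'
#' Replays the argument vector stored in a manifest; deterministic stages
#' reproduce their outputs bitwise (all randomness flows from seeds in
#' the config snapshot).
#'
#' @param manifest_path path to a manifest written by a previous run.
#' @export
rerun_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  plmgraph_main(unlist(man$argv))
}
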