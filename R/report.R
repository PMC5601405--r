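#' Stable digest of a configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON serialisation, so
#' the digest is invariant under key reordering in the config file.
#'
#' @param config A `cua_config`.
#' @return Character MD5 digest.
#' @export
config_digest <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x)) && all(nzchar(names(x)))) x[order(names(x))] else x
    } else x
  }
  json <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                           digits = NA, null = "null")
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: timestamp, command, seeds,
#' configuration digest, package version and output file list.
#'
#' @param config A `cua_config`.
#' @param command Character description of the command run.
#' @param seed Integer seed(s) used (or NULL for deterministic runs).
#' @param outputs Character vector of output file paths.
#' @param path Manifest destination (JSON).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(config, command, seed = NULL, outputs = character(),
                         path = NULL) {
  man <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    seed = seed,
    config_digest = config_digest(config),
    package_version = as.character(utils::packageVersion("gcsfcea")),
    outputs = as.list(outputs)
  )
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

cli_usage <- function() {
  paste(
    "usage: gcsfcea <command> [options]",
    "",
    "commands:",
    "  run-base       base-case cost-utility analysis (both FN risk sources)",
    "  run-owsa       one-way sensitivity analysis (tornado table)",
    "  run-psa        probabilistic sensitivity analysis + CEAC",
    "  run-threshold  price threshold analysis (NMB across stages/ages)",
    "  gen-mortality  write the synthetic mortality tables",
    "",
    "options:",
    "  --config PATH  model configuration (YAML); default: built-in base case",
    "  --fn-risk S    or | rr (FN risk estimate source, run-base)",
    "  --out DIR      output directory (default gcsfcea-out)",
    "  --n N          PSA draws (default 5000)",
    "  --seed S       master seed (default 1)",
    "  --wtp W        willingness-to-pay per QALY (default 30000)",
    sep = "\n")
}

cli_parse <- function(args) {
  opts <- list(config = NULL, fn_risk = NULL, out = "gcsfcea-out",
               n = 5000L, seed = 1L, wtp = 30000)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1; if (i > length(args)) stop("missing value for ", a, call. = FALSE); args[i] }
    switch(a,
      "--config" = opts$config <- take(),
      "--fn-risk" = opts$fn_risk <- take(),
      "--out" = opts$out <- take(),
      "--n" = opts$n <- as.integer(take()),
      "--seed" = opts$seed <- as.integer(take()),
      "--wtp" = opts$wtp <- as.numeric(take()),
      stop("unknown flag: ", a, call. = FALSE))
    i <- i + 1
  }
  opts
}

#' Command-line entry point
#'
#' Thin shell interface over the package functions; see
#' `inst/cli/gcsfcea` for the executable wrapper. Every run writes tidy
#' CSV outputs plus a JSON manifest (seed, config digest, file list) to
#' the output directory.
#'
#' @param args Character vector of command-line arguments (first
#'   element the subcommand).
#' @return Integer exit code (0 success, 1 runtime/validation failure,
#'   2 usage error), invisibly.
#' @export
cua_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !args[1] %in% c("run-base", "run-owsa", "run-psa", "run-threshold",
                      "gen-mortality")) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- args[1]
  opts <- tryCatch(cli_parse(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message("error: ", conditionMessage(opts), "\n\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- if (is.null(opts$config)) base_case_config() else load_config(opts$config)
    if (!is.null(opts$fn_risk))
      cfg$fn_risk_estimate_source <-
        switch(opts$fn_risk, or = "direct_or", rr = "direct_rr",
               stop("--fn-risk must be 'or' or 'rr'", call. = FALSE))
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    outputs <- cli_dispatch(cmd, cfg, opts)
    run_manifest(cfg, paste(c("gcsfcea", args), collapse = " "),
                 seed = if (cmd == "run-psa") opts$seed else NULL,
                 outputs = outputs,
                 path = file.path(opts$out, "manifest.json"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_dispatch <- function(cmd, cfg, opts) {
  out <- opts$out
  lt <- generate_life_table()
  bc <- generate_bc_mortality()
  w <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  if (cmd == "run-base") {
    rows <- list()
    for (src in c("direct_or", "direct_rr")) {
      cfg$fn_risk_estimate_source <- src
      res <- run_base_case(cfg, lt, bc, wtp = opts$wtp)
      print(res)
      for (o in list(res$lipegfilgrastim, res$pegfilgrastim))
        rows[[paste(src, o$arm)]] <- data.frame(
          fn_risk_source = src, arm = o$arm, cost = o$cost,
          qalys = o$qalys, ly = o$ly)
      rows[[paste(src, "difference")]] <- data.frame(
        fn_risk_source = src, arm = "difference",
        cost = res$incremental$delta_cost,
        qalys = res$incremental$delta_qalys, ly = res$incremental$delta_ly)
    }
    return(w(do.call(rbind, rows), "base_case.csv"))
  }
  if (cmd == "run-owsa") {
    tor <- owsa(cfg, life_table = lt, bc_table = bc)
    return(w(as.data.frame(tor), "tornado.csv"))
  }
  if (cmd == "run-psa") {
    psa <- run_psa(cfg, n_draws = opts$n, seed = opts$seed,
                   life_table = lt, bc_table = bc)
    print(psa)
    p1 <- w(psa$draws, "psa_draws.csv")
    p2 <- w(ceac(psa, cfg$wtp_grid), "ceac.csv")
    return(c(p1, p2))
  }
  if (cmd == "run-threshold") {
    th <- price_threshold(cfg, wtp = opts$wtp, life_table = lt, bc_table = bc)
    print(th)
    return(w(th$cells, "threshold.csv"))
  }
  # gen-mortality (deterministic generators, no seed)
  p1 <- file.path(out, "life_table.csv"); write_life_table(lt, p1)
  p2 <- file.path(out, "bc_mortality.csv"); write_bc_mortality(bc, p2)
  c(p1, p2)
}
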