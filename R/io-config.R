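#' Serialize a simulation configuration as a flat key-value file
#'
#' One `key = value` pair per line; vectors are comma-separated, surveys are
#' stored as indexed blocks (`survey1.year`, `survey1.counties`, ...). The
#' adjacency graph travels separately as an edge list
#' (see [write_adjacency()]).
#'
#' @param config a [sim_config].
#' @param path file path.
#' @param graph a [u5m_graph] used when reading back.
#' @return `read_sim_config()` returns a [sim_config].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  num <- function(x) paste(format(x, digits = 15, scientific = FALSE,
                                  trim = TRUE), collapse = ",")
  lines <- c(
    paste0("year_min=", config$year_range[1L]),
    paste0("year_max=", config$year_range[2L]),
    paste0("alpha=", num(config$alpha)),
    paste0("sigma2_S=", num(config$sigma2_S)),
    paste0("rho_s=", num(config$rho_s)),
    paste0("phi_t=", num(config$phi_t)),
    paste0("tau2_methods=", paste(names(config$tau2_by_method), collapse = ",")),
    paste0("tau2_values=", num(config$tau2_by_method)),
    paste0("hazard_split=", num(config$hazard_split)),
    paste0("fertility_groups=", paste(names(config$fertility_rates), collapse = ",")),
    paste0("fertility_rates=", num(config$fertility_rates)),
    paste0("seed=", config$seed))
  for (i in seq_along(config$surveys)) {
    s <- config$surveys[[i]]
    lines <- c(lines,
               paste0("survey", i, ".id=", s$id),
               paste0("survey", i, ".year=", s$year),
               paste0("survey", i, ".counties=", paste(s$counties, collapse = ",")),
               paste0("survey", i, ".women=", s$women),
               paste0("survey", i, ".cbh=", s$collects_cbh),
               paste0("survey", i, ".sbh=", s$collects_sbh))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path, graph) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("config key missing: ", k)
    vals[i]
  }
  nums <- function(k) as.numeric(strsplit(get1(k), ",")[[1L]])
  chars <- function(k) strsplit(get1(k), ",")[[1L]]
  n_s <- sum(grepl("^survey[0-9]+\\.year$", keys))
  surveys <- lapply(seq_len(n_s), function(i) {
    p <- paste0("survey", i, ".")
    survey_spec(as.integer(get1(paste0(p, "year"))),
                chars(paste0(p, "counties")),
                as.integer(get1(paste0(p, "women"))),
                collects_cbh = as.logical(get1(paste0(p, "cbh"))),
                collects_sbh = as.logical(get1(paste0(p, "sbh"))),
                id = get1(paste0(p, "id")))
  })
  sim_config(graph,
             year_range = c(as.integer(get1("year_min")),
                            as.integer(get1("year_max"))),
             alpha = nums("alpha"), sigma2_S = nums("sigma2_S"),
             rho_s = nums("rho_s"), phi_t = nums("phi_t"),
             tau2_by_method = stats::setNames(nums("tau2_values"),
                                              chars("tau2_methods")),
             hazard_split = nums("hazard_split"),
             fertility_rates = stats::setNames(nums("fertility_rates"),
                                               chars("fertility_groups")),
             surveys = surveys, seed = as.integer(get1("seed")))
}
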