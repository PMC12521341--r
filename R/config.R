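# Plain-text configuration files.
#
# One human-editable key-value document per run.  Numeric entries are
# written as full-precision decimal strings (17 significant digits), so a
# write/read round trip reproduces every double bit-exactly.  Matrices are
# written inline, rows separated by ';'.

#' @noRd
fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' @noRd
fmt_vec <- function(x) paste(fmt_num(x), collapse = " ")

#' @noRd
fmt_mat <- function(m) {
  paste(apply(m, 1, fmt_vec), collapse = " ; ")
}

#' @noRd
parse_vec <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' @noRd
parse_mat <- function(s) {
  rows <- strsplit(s, ";")[[1]]
  do.call(rbind, lapply(rows, parse_vec))
}

#' @noRd
config_lines_model <- function(model) {
  ln <- c("[model]",
          sprintf("n = %d", model$n),
          sprintf("m = %d", model$m),
          sprintf("populations = %s",
                  paste(model$labels$populations, collapse = " ")),
          sprintf("drugs = %s", paste(model$labels$drugs, collapse = " ")),
          sprintf("scale = %s", fmt_num(model$scale)),
          sprintf("A = %s", fmt_mat(model$A)))
  if (any(model$B != 0)) ln <- c(ln, sprintf("B = %s", fmt_mat(model$B)))
  for (i in seq_len(model$n)) {
    if (any(model$C[[i]] != 0)) {
      ln <- c(ln, sprintf("C%d = %s", i, fmt_mat(model$C[[i]])))
    }
  }
  for (i in seq_len(model$n)) for (j in seq_len(model$n)) {
    if (any(model$D[[i]][[j]] != 0)) {
      ln <- c(ln, sprintf("D%d.%d = %s", i, j, fmt_mat(model$D[[i]][[j]])))
    }
  }
  ln
}

#' Write a model to a plain-text configuration file
#'
#' @param model a [controlled_ode_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model_config()]
#' @export
write_model_config <- function(model, path) {
  writeLines(c("# octherapy model configuration",
               config_lines_model(model)), path)
  invisible(path)
}

#' Parse config lines into a list of named sections of key/value strings.
#' @noRd
parse_config_sections <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    sec <- regmatches(ln, regexec("^\\s*\\[(\\w+)\\]\\s*$", ln))[[1]]
    if (length(sec) == 2L) {
      current <- sec[2]
      sections[[current]] <- character(0)
      next
    }
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L || is.null(current)) {
      stop(sprintf("malformed configuration line: '%s'", ln))
    }
    sections[[current]][kv[2]] <- trimws(kv[3])
  }
  sections
}

#' @noRd
model_from_section <- function(sec) {
  n <- as.integer(sec[["n"]]); m <- as.integer(sec[["m"]])
  getm <- function(key, nr, nc) {
    if (is.na(sec[key])) return(matrix(0, nr, nc))
    mt <- parse_mat(sec[[key]])
    if (!all(dim(mt) == c(nr, nc))) {
      stop(sprintf("config matrix %s has dimensions %dx%d; expected %dx%d",
                   key, nrow(mt), ncol(mt), nr, nc))
    }
    mt
  }
  C <- lapply(seq_len(n), function(i) getm(paste0("C", i), n, m))
  D <- lapply(seq_len(n), function(i) {
    lapply(seq_len(n), function(j) getm(sprintf("D%d.%d", i, j), m, m))
  })
  controlled_ode_model(
    A = getm("A", n, n), B = getm("B", n, m), C = C, D = D, m = m,
    labels = list(
      populations = strsplit(sec[["populations"]], "\\s+")[[1]],
      drugs = strsplit(sec[["drugs"]], "\\s+")[[1]]),
    scale = as.numeric(sec[["scale"]]))
}

#' Read a model from a plain-text configuration file
#'
#' @param path file written by [write_model_config()] (or hand-edited in
#'   the same format).
#' @return A [controlled_ode_model()].
#' @export
read_model_config <- function(path) {
  sections <- parse_config_sections(readLines(path))
  if (is.null(sections$model)) stop("configuration has no [model] section")
  model_from_section(sections$model)
}

#' Write a full problem (model + cost + initial state) configuration
#'
#' @param problem an [oc_problem()] or [proportion_problem()].
#' @param path output file path.
#' @param settings optional [oc_solver_settings()] stored in a `[solver]`
#'   section.
#' @return `path`, invisibly.
#' @export
write_problem_config <- function(problem, path, settings = NULL) {
  is_prop <- inherits(problem, "proportion_problem")
  ln <- c("# octherapy problem configuration",
          config_lines_model(problem$model),
          "[cost]",
          sprintf("T = %s", fmt_num(problem$cost$T)),
          sprintf("Q = %s", fmt_mat(cost_Q(problem$cost))),
          sprintf("R = %s", fmt_mat(cost_R(problem$cost))),
          sprintf("M = %s", fmt_mat(problem$cost$M)),
          "[problem]",
          sprintf("type = %s", if (is_prop) "proportion" else "count"),
          sprintf("x0 = %s", fmt_vec(problem$x0)),
          sprintf("lower = %s", fmt_vec(problem$lower)),
          sprintf("upper = %s", fmt_vec(problem$upper)))
  if (is_prop) {
    ln <- c(ln, sprintf("target = %s", fmt_vec(problem$target)))
  }
  if (!is.null(settings)) {
    ln <- c(ln, "[solver]",
            sprintf("n_nodes = %d", settings$n_nodes),
            sprintf("max_iter = %d", settings$max_iter),
            sprintf("tol = %s", fmt_num(settings$tol)))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a problem configuration
#'
#' Validation failures name the offending matrix or field (for example a
#' control penalty `R` that is not positive definite).
#'
#' @param path configuration file path.
#' @return A list with `problem` (an [oc_problem()] or
#'   [proportion_problem()]) and `settings` (an [oc_solver_settings()], or
#'   `NULL` when the file carries no `[solver]` section).
#' @export
read_problem_config <- function(path) {
  sections <- parse_config_sections(readLines(path))
  for (need in c("model", "cost", "problem")) {
    if (is.null(sections[[need]])) {
      stop(sprintf("configuration has no [%s] section", need))
    }
  }
  model <- model_from_section(sections$model)
  cs <- sections$cost
  ps <- sections$problem
  type <- if (!is.na(ps["type"])) ps[["type"]] else "count"
  bounds <- list(lower = parse_vec(ps[["lower"]]),
                 upper = parse_vec(ps[["upper"]]))
  if (type == "proportion") {
    problem <- proportion_problem(
      model, target = parse_vec(ps[["target"]]),
      W_state = parse_mat(cs[["Q"]]), W_control = parse_mat(cs[["R"]]),
      T = as.numeric(cs[["T"]]), r0 = parse_vec(ps[["x0"]]),
      control_bounds = bounds)
  } else {
    M <- if (!is.na(cs["M"])) parse_mat(cs[["M"]]) else NULL
    cost <- cost_spec(Q = parse_mat(cs[["Q"]]), R = parse_mat(cs[["R"]]),
                      M = M, T = as.numeric(cs[["T"]]))
    problem <- oc_problem(model, cost, x0 = parse_vec(ps[["x0"]]),
                          control_bounds = bounds)
  }
  settings <- NULL
  if (!is.null(sections$solver)) {
    ss <- sections$solver
    settings <- oc_solver_settings(
      n_nodes = if (!is.na(ss["n_nodes"])) as.integer(ss[["n_nodes"]]) else 241L,
      max_iter = if (!is.na(ss["max_iter"])) as.integer(ss[["max_iter"]]) else 60L,
      tol = if (!is.na(ss["tol"])) as.numeric(ss[["tol"]]) else 1e-8)
  }
  list(problem = problem, settings = settings, type = type)
}
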