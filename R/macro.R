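#' Recordable, replayable processing pipelines
#'
#' A macro is an ordered list of named operations with explicit parameters,
#' input and output file slots, and a seed, serialised as JSON. Replaying a
#' macro on identical inputs reproduces the outputs bit-identically, which is
#' the contract needed for batch processing of large acquisition series.
#' Operations are validated against the registry before any I/O happens.
#'
#' @param schema_version macro schema version string.
#' @return `macro_new()` returns an empty macro (class `deepvox_macro`).
#' @export
macro_new <- function(schema_version = "1") {
  structure(list(schema_version = schema_version,
                 tool = paste0("deepvox ",
                               as.character(utils::packageVersion("deepvox"))),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 steps = list()),
            class = "deepvox_macro")
}

#' @rdname macro_new
#' @param macro a macro.
#' @param op registered operation name (see [macro_ops()]).
#' @param inputs named character vector/list of input slots (file names,
#'   relative to the replay input directory).
#' @param outputs named character vector/list of output slots.
#' @param params named list of parameters for the operation.
#' @param seed optional integer seed recorded with the step.
#' @export
macro_add <- function(macro, op, inputs = list(), outputs = list(),
                      params = list(), seed = NULL) {
  stopifnot(inherits(macro, "deepvox_macro"))
  validate_step(op, inputs, outputs, params)
  macro$steps[[length(macro$steps) + 1L]] <-
    list(op = op, inputs = as.list(inputs), outputs = as.list(outputs),
         params = params, seed = seed)
  macro
}

#' @rdname macro_new
#' @export
macro_ops <- function() names(op_registry())

validate_step <- function(op, inputs, outputs, params) {
  reg <- op_registry()
  if (!op %in% names(reg))
    stop(sprintf("unknown operation '%s'; known: %s", op,
                 paste(names(reg), collapse = ", ")))
  spec <- reg[[op]]
  miss <- setdiff(spec$inputs, names(inputs))
  if (length(miss))
    stop(sprintf("op '%s': missing input slot(s) %s", op,
                 paste(miss, collapse = ", ")))
  misso <- setdiff(spec$outputs, names(outputs))
  if (length(misso))
    stop(sprintf("op '%s': missing output slot(s) %s", op,
                 paste(misso, collapse = ", ")))
  badp <- setdiff(names(params), spec$params)
  if (length(badp))
    stop(sprintf("op '%s': unknown parameter(s) %s", op,
                 paste(badp, collapse = ", ")))
  invisible(TRUE)
}

op_registry <- function() {
  list(
    enhance_global = list(
      inputs = "image", outputs = "image",
      params = c("p_min", "p_max"),
      run = function(ins, outs, params, seed) {
        img <- read_stack(ins$image)
        write_stack(do.call(enhance_global, c(list(img), params)),
                    outs$image)
      }),
    enhance_local = list(
      inputs = "image", outputs = "image",
      params = c("w", "p_min", "p_max", "stride"),
      run = function(ins, outs, params, seed) {
        img <- read_stack(ins$image)
        write_stack(do.call(enhance_local, c(list(img), params)), outs$image)
      }),
    resample_isotropic = list(
      inputs = "image", outputs = "image", params = "target",
      run = function(ins, outs, params, seed) {
        img <- read_stack(ins$image)
        write_stack(resample_isotropic(img, params$target), outs$image)
      }),
    smooth_dense = list(
      inputs = "image", outputs = "image", params = c("sigma", "a_factor"),
      run = function(ins, outs, params, seed) {
        img <- read_stack(ins$image)
        write_stack(do.call(smooth_dense, c(list(img), params)), outs$image)
      }),
    smooth_masked = list(
      inputs = c("image", "mask"), outputs = "image",
      params = c("sigma", "a_factor"),
      run = function(ins, outs, params, seed) {
        img <- read_stack(ins$image)
        msk <- read_stack(ins$mask)
        write_stack(do.call(smooth_masked,
                            c(list(img, unclass_arr(msk) != 0), params)),
                    outs$image)
      }),
    normalize = list(
      inputs = c("image", "reference", "nuclei_labels"),
      outputs = "image", params = c("r", "sigma"),
      run = function(ins, outs, params, seed) {
        img <- read_stack(ins$image)
        ref <- read_stack(ins$reference)
        lab <- read_stack(ins$nuclei_labels, labels = TRUE)
        m_nuc <- unclass_arr_int(lab) > 0L
        sig <- if (is.null(params$sigma)) select_sigma(ref, m_nuc) else
          params$sigma
        rf <- reference_field(ref, m_nuc, sig)
        write_stack(normalize_channel(img, rf, params$r), outs$image)
      }),
    register_fuse = list(
      inputs = c("reference", "floating", "landmarks"),
      outputs = "image", params = c("p", "z0", "preset"),
      run = function(ins, outs, params, seed) {
        ref <- read_stack(ins$reference)
        flt <- read_stack(ins$floating)
        lm <- utils::read.csv(ins$landmarks)
        T <- fit_rigid_landmarks(as.matrix(lm[, c("src_z", "src_y", "src_x")]),
                                 as.matrix(lm[, c("dst_z", "dst_y", "dst_x")]))
        moved <- apply_rigid(flt, T,
                             output_grid = list(dim = dim(ref),
                                                spacing = vox_spacing(ref)))
        p <- if (is.null(params$p)) 15 else params$p
        z0 <- if (is.null(params$z0)) 0.5 else params$z0
        write_stack(fuse_sigmoid(ref, moved, p = p, z0 = z0), outs$image)
      }),
    phantom = list(
      inputs = character(0), outputs = "dir", params = "spec",
      run = function(ins, outs, params, seed) {
        args <- params$spec
        if (!is.null(seed)) args$seed <- seed
        ph <- generate_phantom(do.call(phantom_spec, args))
        write_phantom(ph, outs$dir)
      })
  )
}

#' @rdname macro_new
#' @param path JSON file path.
#' @export
macro_write <- function(macro, path) {
  jsonlite::write_json(unclass(macro), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname macro_new
#' @export
macro_read <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$schema_version))
    stop("not a macro file: missing schema_version")
  if (!identical(as.character(j$schema_version), "1"))
    stop(sprintf("unsupported macro schema version '%s'", j$schema_version))
  m <- structure(list(schema_version = j$schema_version, tool = j$tool,
                      created = j$created, steps = list()),
                 class = "deepvox_macro")
  for (s in j$steps)
    m <- macro_add(m, s$op, inputs = s$inputs, outputs = s$outputs,
                   params = lapply(s$params, function(p)
                     if (is.list(p)) p else unlist(p)),
                   seed = s$seed)
  m
}

#' @rdname macro_new
#' @param input_dir directory resolving relative input slots.
#' @param output_dir directory for output slots (created if needed).
#' @param log_path optional JSON-lines log file recording each executed step
#'   with parameters and seeds.
#' @return `macro_replay()` returns the vector of written output paths,
#'   invisibly.
#' @export
macro_replay <- function(macro, input_dir = ".", output_dir = ".",
                         log_path = NULL) {
  stopifnot(inherits(macro, "deepvox_macro"))
  reg <- op_registry()
  for (s in macro$steps)
    validate_step(s$op, s$inputs, s$outputs, s$params)  # validate all first
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  produced <- character(0)  # slots produced by earlier steps live in output_dir
  for (i in seq_along(macro$steps)) {
    s <- macro$steps[[i]]
    ins <- lapply(s$inputs, function(f)
      if (f %in% produced) file.path(output_dir, f) else file.path(input_dir, f))
    outs <- lapply(s$outputs, function(f) file.path(output_dir, f))
    runner <- function() reg[[s$op]]$run(ins, outs, s$params, s$seed)
    if (!is.null(s$seed)) with_seed(as.integer(s$seed), runner()) else runner()
    produced <- c(produced, unlist(s$outputs))
    written <- c(written, unlist(outs))
    if (!is.null(log_path)) {
      line <- jsonlite::toJSON(list(step = i, op = s$op, params = s$params,
                                    seed = s$seed, outputs = unlist(outs),
                                    tool = macro$tool),
                               auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = log_path, append = TRUE)
    }
  }
  invisible(written)
}

#' @export
print.deepvox_macro <- function(x, ...) {
  cat(sprintf("<deepvox_macro> schema %s, %d step(s)\n", x$schema_version,
              length(x$steps)))
  for (i in seq_along(x$steps))
    cat(sprintf("  %d. %s(%s)\n", i, x$steps[[i]]$op,
                paste(names(x$steps[[i]]$params), collapse = ", ")))
  invisible(x)
}
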