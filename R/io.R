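# Plain-text and PNG I/O for patches, texture vectors, trial data, and
# models. All formats are human-readable (whitespace grids, CSV, JSON) or
# standard PNG.

#' Read and write gray patches as plain-text integer grids
#'
#' @param patch A `gray_patch`.
#' @param path File path.
#' @param G Number of gray levels (when reading).
#' @return `read_patch_txt` returns a `gray_patch`.
#' @export
write_patch_txt <- function(patch, path) {
  utils::write.table(unclass(patch), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_txt
#' @export
read_patch_txt <- function(path, G = 3L) {
  gray_patch(as.matrix(utils::read.table(path)), G = G)
}

#' Read and write gray patches as PNG images
#'
#' Levels are mapped linearly onto gray values: 0 to black, `G-1` to white
#' (for G = 3 the middle level is mid-gray).
#'
#' @param patch A `gray_patch`.
#' @param path File path.
#' @param G Number of gray levels (when reading).
#' @return `read_patch_png` returns a `gray_patch`.
#' @export
write_patch_png <- function(patch, path) {
  G <- patch_G(patch)
  png::writePNG(unclass(patch) / (G - 1), path)
  invisible(path)
}

#' @rdname write_patch_png
#' @export
read_patch_png <- function(path, G = 3L) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  gray_patch(round(m * (G - 1)), G = G)
}

#' Read a grayscale image (PNG or plain-text matrix) as a numeric matrix
#'
#' @param path File path; `.png` is read via the png package (values in
#'   0..1), anything else as a whitespace-separated numeric grid.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  } else {
    as.matrix(utils::read.table(path))
  }
}

#' Serialize texture vectors to CSV or JSON
#'
#' The CSV has columns `group_id`, `group`, `h`, `probability`; the JSON is a
#' flat named list. Both round-trip through the corresponding readers.
#'
#' @param v A `texture_vector`.
#' @param path File path.
#' @param G Number of gray levels (when reading).
#' @return Readers return a `texture_vector`.
#' @export
write_texture_vector_csv <- function(v, path) {
  G <- attr(v, "G")
  ids <- attr(v, "group_ids")
  df <- data.frame(group_id = rep(ids, each = G),
                   group = rep(vapply(tv_groups(v), `[[`, character(1), "name"),
                               each = G),
                   h = rep(0:(G - 1), length(ids)),
                   probability = as.numeric(v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_texture_vector_csv
#' @export
read_texture_vector_csv <- function(path, G = 3L) {
  df <- utils::read.csv(path)
  groups <- lapply(unique(df$group_id), texture_group, G = G)
  ord <- order(match(df$group_id, unique(df$group_id)), df$h)
  new_texture_vector(df$probability[ord], groups, G)
}

#' @rdname write_texture_vector_csv
#' @export
write_texture_vector_json <- function(v, path) {
  jsonlite::write_json(as.list(stats::setNames(as.numeric(v), names(v))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

direction_to_fields <- function(d) {
  if (d$type == "simple")
    data.frame(plane_type = "simple", group_a = d$group_a$id, h_a = NA,
               group_b = NA, h_b = NA, angle = d$angle)
  else
    data.frame(plane_type = "mixed", group_a = d$group_a$id, h_a = d$h_a,
               group_b = d$group_b$id, h_b = d$h_b, angle = d$angle)
}

direction_from_fields <- function(row, G = 3L) {
  if (row$plane_type == "simple")
    plane_direction(texture_group(row$group_a, G), angle = row$angle, G = G)
  else
    plane_direction(texture_group(row$group_a, G), angle = row$angle,
                    h_a = row$h_a, group_b = texture_group(row$group_b, G),
                    h_b = row$h_b, G = G)
}

#' Serialize 4AFC trial blocks to CSV
#'
#' Columns: subject, plane_type, group_a, h_a, group_b, h_b, angle, contrast,
#' n_trials, n_correct (one row per tested contrast).
#'
#' @param blocks List of `trial_block`s.
#' @param path File path.
#' @param G Number of gray levels (when reading).
#' @return `read_trial_blocks_csv` returns a list of `trial_block`s.
#' @export
write_trial_blocks_csv <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    dir_df <- if (is.null(b$direction))
      data.frame(plane_type = NA, group_a = NA, h_a = NA, group_b = NA,
                 h_b = NA, angle = NA)
    else direction_to_fields(b$direction)
    cbind(subject = b$subject, dir_df[rep(1, length(b$contrasts)), ],
          data.frame(contrast = b$contrasts, n_trials = b$n_trials,
                     n_correct = b$n_correct))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_blocks_csv
#' @export
read_trial_blocks_csv <- function(path, G = 3L) {
  df <- utils::read.csv(path)
  key <- paste(df$subject, df$plane_type, df$group_a, df$h_a, df$group_b,
               df$h_b, df$angle)
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    dir <- if (is.na(d$plane_type[1])) NULL
           else direction_from_fields(d[1, ], G = G)
    trial_block(d$contrast, d$n_trials, d$n_correct, direction = dir,
                subject = d$subject[1])
  })
}

#' Serialize a Gaussian texture model to JSON
#'
#' Stores the mean, covariance, coordinate names, and the coordinate-ordering
#' version so downstream consumers can verify compatibility.
#'
#' @param model A `gaussian_texture_model`.
#' @param path File path.
#' @return `read_model_json` returns a `gaussian_texture_model`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(coordinate_ordering = "gliderstats-v1",
                            names = names(model$mean),
                            mean = as.numeric(model$mean),
                            cov = model$cov, n = model$n, ridge = model$ridge),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$coordinate_ordering, "gliderstats-v1"))
    stop("unknown coordinate ordering version: ", x$coordinate_ordering)
  structure(list(mean = stats::setNames(x$mean, x$names),
                 cov = as.matrix(x$cov), n = x$n, ridge = x$ridge),
            class = "gaussian_texture_model")
}
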