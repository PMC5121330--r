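# The residue feature schema: an ordered list of channels, each with a
# per-residue dimensionality, an odd centred window width and a padding
# value used beyond the termini. The default schema totals exactly 246
# features; any schema with the same column contract is pluggable.

#' Construct a feature schema
#'
#' @param channels Tibble (or data frame) with columns `channel` (name),
#'   `dims` (values per residue), `window` (odd centred window width) and
#'   `padding` (value used beyond the termini).
#' @return The validated schema tibble, class `na_schema`, with attribute
#'   `total` = `sum(dims * window)`.
#' @export
feature_schema <- function(channels) {
  ch <- tibble::as_tibble(channels)
  stopifnot(all(c("channel", "dims", "window", "padding") %in% names(ch)))
  if (anyDuplicated(ch$channel)) stop("duplicate channel names", call. = FALSE)
  if (any(ch$window %% 2 != 1)) stop("window widths must be odd", call. = FALSE)
  if (any(ch$dims < 1)) stop("dims must be >= 1", call. = FALSE)
  attr(ch, "total") <- sum(ch$dims * ch$window)
  class(ch) <- c("na_schema", setdiff(class(ch), "na_schema"))
  ch
}

#' Total feature count of a schema
#' @param schema An `na_schema`.
#' @return Integer: the assembled vector length.
#' @export
schema_total <- function(schema) as.integer(attr(schema, "total"))

#' The default 246-feature residue schema
#'
#' Channels, in column order: amino-acid one-hot (20 x window 9 = 180),
#' conservation (window 9), entropy (window 9), log10 alignment depth
#' (chain-level, 1), three-state secondary structure (3 x window 7 = 21),
#' disorder (window 7), accessibility (2 x window 7 = 14) and
#' physicochemical descriptors of the central residue (5);
#' 180 + 9 + 9 + 1 + 21 + 7 + 14 + 5 = 246. Windows follow the
#' profile-width-9 / structure-width-7 convention; padding beyond the
#' termini is 0 for every channel (an all-zero one-hot). A relative
#' terminal-distance channel (`term_dist`) is additionally available to
#' custom schemas.
#'
#' The same schema ships as a machine-readable YAML file under
#' `system.file("extdata", "feature_schema.yaml", package = "nabind")`.
#'
#' @return An `na_schema` with `schema_total()` 246.
#' @examples
#' schema_total(default_feature_schema())
#' @export
default_feature_schema <- function() {
  feature_schema(tibble::tibble(
    channel = c("aa", "conservation", "entropy", "n_align", "ss3",
                "disorder", "accessibility", "physchem"),
    dims    = c(20L, 1L, 1L, 1L, 3L, 1L, 2L, 5L),
    window  = c(9L, 9L, 9L, 1L, 7L, 7L, 7L, 1L),
    padding = rep(0, 8)
  ))
}

#' Read / write a feature schema as YAML
#'
#' @param path YAML file path.
#' @return `read_feature_schema()` returns an `na_schema`;
#'   `write_feature_schema()` returns `path` invisibly.
#' @export
read_feature_schema <- function(path) {
  y <- yaml::read_yaml(path)
  feature_schema(dplyr::bind_rows(lapply(y$channels, tibble::as_tibble)))
}

#' @rdname read_feature_schema
#' @param schema An `na_schema` to serialise.
#' @export
write_feature_schema <- function(schema, path) {
  y <- list(channels = lapply(seq_len(nrow(schema)), function(i) {
    list(channel = schema$channel[i], dims = schema$dims[i],
         window = schema$window[i], padding = schema$padding[i])
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

# dimension labels per channel, used for column names
channel_dim_labels <- function(channel, dims) {
  switch(channel,
    aa = AA1,
    ss3 = c("helix", "strand", "other"),
    accessibility = c("rel", "exposed"),
    physchem = c("hydropathy", "charge", "polar", "volume", "hbond"),
    if (dims == 1) "v" else paste0("v", seq_len(dims))
  )
}

#' Column names of an assembled feature vector
#' @param schema An `na_schema`.
#' @return Character vector of length `schema_total(schema)`, in schema
#'   order: channel by channel, window offset by offset, dimension by
#'   dimension.
#' @export
schema_colnames <- function(schema) {
  unlist(lapply(seq_len(nrow(schema)), function(i) {
    w <- schema$window[i]
    offs <- seq.int(-(w %/% 2), w %/% 2)
    labs <- channel_dim_labels(schema$channel[i], schema$dims[i])
    as.vector(t(outer(offs, labs, function(o, l) {
      sprintf("%s_%s_o%+d", schema$channel[i], l, o)
    })))
  }), use.names = FALSE)
}
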