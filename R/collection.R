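# Plain-directory file collection ("database"): registry.json + files/ +
# cache/. Entries are content-addressed (sha256 of the file), so
# re-adding identical content is a no-op; signal files are converted to
# indexed bigWig at add time, features are stored as normalized BED.
# The cache holds one matrix (TSV + JSON manifest) per
# (signal, feature, anchor-fingerprint), mirroring the
# precompute-all-combinations workflow.

#' Open (or create) a file collection
#'
#' @param dir collection directory; created if absent
#' @return a `Collection` handle
#' @export
collection_open <- function(dir) {
  dir.create(file.path(dir, "files"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cache"), showWarnings = FALSE)
  reg <- file.path(dir, "registry.json")
  if (!file.exists(reg))
    jsonlite::write_json(list(), reg, auto_unbox = TRUE)
  structure(list(dir = dir), class = "Collection")
}

registry_read <- function(coll) {
  jsonlite::read_json(file.path(coll$dir, "registry.json"))
}

registry_write <- function(coll, entries) {
  jsonlite::write_json(entries, file.path(coll$dir, "registry.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

file_id <- function(path) digest::digest(path, algo = "sha256", file = TRUE)

#' Add a file to the collection
#'
#' The file is validated by fully parsing it under its format before
#' anything is persisted. Signals arriving as wiggle/bedGraph/BAM are
#' converted to indexed bigWig; features are stored as normalized BED.
#' The entry id is the sha256 of the input content, so adding identical
#' content twice is idempotent.
#'
#' @param coll a [collection_open()] handle
#' @param path input file
#' @param kind `"signal"` or `"feature"` (motif tracks enter via
#'   [collection_add_motif()])
#' @param format explicit format or `"auto"`
#' @param genome_label,user,comment free-text metadata
#' @param label display label (default: file name without extension)
#' @return the `CollectionEntry` (a list), invisibly
#' @export
collection_add <- function(coll, path, kind = c("signal", "feature"),
                           format = "auto", genome_label = "", user = "",
                           comment = "", label = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  id <- file_id(path)
  entries <- registry_read(coll)
  hit <- Filter(function(e) identical(e$id, id), entries)
  if (length(hit) > 0) {
    spl_log("info", "identical content already in collection: ", id)
    return(invisible(hit[[1]]))
  }
  label <- label %||% tools::file_path_sans_ext(basename(path))
  if (kind == "feature") {
    feats <- read_features(path, format, genome_label)  # validates
    stored <- file.path("files", paste0(id, ".bed"))
    write_bed(feats, file.path(coll$dir, stored))
    fmt <- detect_format(path, format, FEATURE_FORMATS)
  } else {
    fmt <- detect_format(path, format, SIGNAL_FORMATS)
    track <- read_signal(path, format)                  # validates
    stored <- file.path("files", paste0(id, ".bw"))
    convert_to_indexed(track, file.path(coll$dir, stored))
  }
  entry <- list(id = id, path = stored, kind = kind, format = fmt,
                label = label, genome_label = genome_label, user = user,
                comment = comment,
                added_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                                  tz = "UTC"))
  registry_write(coll, c(entries, list(entry)))
  spl_log("info", "added ", kind, " '", label, "' as ", id)
  invisible(entry)
}

#' Add a motif-density track to the collection
#'
#' Builds the genome-wide density track with [build_motif_track()],
#' stores it as bigWig, and registers it with `kind = "motif"`.
#'
#' @inheritParams collection_add
#' @param pattern IUPAC pattern
#' @param genome FASTA path
#' @param window,both_strands,per_kb see [motif_spec()]
#' @return the `CollectionEntry`, invisibly
#' @export
collection_add_motif <- function(coll, pattern, genome, window = 200,
                                 both_strands = TRUE, per_kb = TRUE,
                                 genome_label = "", user = "", comment = "",
                                 label = NULL) {
  spec <- motif_spec(pattern, window, both_strands, per_kb)
  track <- build_motif_track(genome, spec)
  tmp <- tempfile(fileext = ".bw")
  convert_to_indexed(track, tmp)
  on.exit(unlink(tmp))
  id <- file_id(tmp)
  entries <- registry_read(coll)
  hit <- Filter(function(e) identical(e$id, id), entries)
  if (length(hit) > 0) return(invisible(hit[[1]]))
  stored <- file.path("files", paste0(id, ".bw"))
  file.copy(tmp, file.path(coll$dir, stored))
  entry <- list(id = id, path = stored, kind = "motif", format = "bigwig",
                label = label %||% sprintf("%s density (w=%d)", spec$pattern,
                                           spec$window),
                genome_label = genome_label, user = user, comment = comment,
                added_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                                  tz = "UTC"))
  registry_write(coll, c(entries, list(entry)))
  invisible(entry)
}

#' List collection entries
#'
#' @param coll a `Collection`
#' @param kind optional filter: `"signal"`, `"feature"` or `"motif"`
#' @param text optional case-insensitive substring matched against
#'   label, comment and user
#' @param genome optional exact genome-label filter
#' @return tibble of entries, stably sorted by `added_at` then id
#' @export
collection_list <- function(coll, kind = NULL, text = NULL, genome = NULL) {
  entries <- registry_read(coll)
  df <- tibble::tibble(
    id = vapply(entries, `[[`, character(1), "id"),
    label = vapply(entries, `[[`, character(1), "label"),
    kind = vapply(entries, `[[`, character(1), "kind"),
    format = vapply(entries, `[[`, character(1), "format"),
    genome_label = vapply(entries, `[[`, character(1), "genome_label"),
    user = vapply(entries, `[[`, character(1), "user"),
    comment = vapply(entries, `[[`, character(1), "comment"),
    added_at = vapply(entries, `[[`, character(1), "added_at"),
    path = vapply(entries, `[[`, character(1), "path"))
  if (!is.null(kind)) df <- df[df$kind %in% kind, ]
  if (!is.null(genome)) df <- df[df$genome_label == genome, ]
  if (!is.null(text)) {
    pat <- tolower(text)
    hay <- tolower(paste(df$label, df$comment, df$user))
    df <- df[grepl(pat, hay, fixed = TRUE), ]
  }
  df[order(df$added_at, df$id), ]
}

#' Look up one collection entry by id or label
#' @param coll a `Collection`
#' @param id_or_label entry id (content hash) or display label
#' @return the entry (a list); error if absent
#' @export
collection_entry <- function(coll, id_or_label) {
  entries <- registry_read(coll)
  for (e in entries)
    if (identical(e$id, id_or_label) || identical(e$label, id_or_label))
      return(e)
  stopf("no collection entry with id or label '%s'", id_or_label)
}

#' Load a stored signal or motif track from the collection
#' @inheritParams collection_entry
#' @return a [signal_track()]
#' @export
collection_load_track <- function(coll, id_or_label) {
  e <- collection_entry(coll, id_or_label)
  if (!e$kind %in% c("signal", "motif"))
    stopf("entry '%s' is a %s, not a signal", id_or_label, e$kind)
  read_signal(file.path(coll$dir, e$path), "bigwig")
}

#' Load a stored feature set from the collection
#' @inheritParams collection_entry
#' @return a `GRanges` (see [read_features()])
#' @export
collection_load_features <- function(coll, id_or_label) {
  e <- collection_entry(coll, id_or_label)
  if (e$kind != "feature")
    stopf("entry '%s' is a %s, not a feature set", id_or_label, e$kind)
  read_features(file.path(coll$dir, e$path), "bed", e$genome_label)
}

pair_fingerprint <- function(signal_id, feature_id, anchor) {
  digest::digest(list(signal = signal_id, feature = feature_id,
                      anchor = unclass(anchor)), algo = "sha256")
}

save_matrix_cache <- function(matrix, cache_dir, fp, signal_id, feature_id) {
  utils::write.table(matrix$values,
                     file.path(cache_dir, paste0(fp, ".tsv")),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    fingerprint = fp, signal_id = signal_id, feature_id = feature_id,
    signal_label = matrix$signal_label, feature_label = matrix$feature_label,
    anchor = unclass(matrix$anchor), bin_centers = matrix$bin_centers,
    feature_ids = matrix$feature_ids),
    file.path(cache_dir, paste0(fp, ".json")), auto_unbox = TRUE, digits = NA)
}

load_matrix_cache <- function(cache_dir, fp) {
  man_path <- file.path(cache_dir, paste0(fp, ".json"))
  if (!file.exists(man_path)) return(NULL)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(
    file.path(cache_dir, paste0(fp, ".tsv")), sep = "\t"))
  dimnames(values) <- NULL
  anchor <- do.call(anchor_spec, man$anchor[c("mode", "upstream",
                                              "downstream", "bin",
                                              "body_bins", "ignore_strand")])
  structure(list(values = values, bin_centers = man$bin_centers,
                 feature_ids = man$feature_ids,
                 signal_label = man$signal_label,
                 feature_label = man$feature_label, anchor = anchor),
            class = "ProfileMatrix")
}

#' Precompute the signal x feature matrix grid
#'
#' Computes and caches a `ProfileMatrix` for every combination of the
#' given signals and features under one anchor spec. Pairs already
#' cached under the same fingerprint (a pure function of signal content
#' hash, feature content hash and the anchor fields) are skipped; a
#' failing pair is logged and the remaining pairs still run.
#'
#' @param coll a `Collection`
#' @param signals,features vectors of entry ids or labels
#' @param anchor an [anchor_spec()]
#' @return a `GridCache`: tibble with one row per pair (`signal`,
#'   `feature`, `fingerprint`, `computed` flag, `ok` flag, seconds);
#'   attribute `cache_dir` points at the stored matrices
#' @export
precompute <- function(coll, signals, features, anchor) {
  cache_dir <- file.path(coll$dir, "cache")
  rows <- list()
  feat_objs <- lapply(features, function(f) collection_load_features(coll, f))
  for (si in signals) {
    se <- collection_entry(coll, si)
    track <- NULL
    for (j in seq_along(features)) {
      fe <- collection_entry(coll, features[[j]])
      fp <- pair_fingerprint(se$id, fe$id, anchor)
      cached <- file.exists(file.path(cache_dir, paste0(fp, ".json")))
      t0 <- proc.time()[["elapsed"]]
      ok <- TRUE
      if (!cached) {
        ok <- tryCatch({
          if (is.null(track)) track <- collection_load_track(coll, si)
          m <- compute_matrix(feat_objs[[j]], track, anchor,
                              signal_label = se$label,
                              feature_label = fe$label)
          save_matrix_cache(m, cache_dir, fp, se$id, fe$id)
          TRUE
        }, error = function(err) {
          spl_log("warn", "pair ", se$label, " x ", fe$label,
                  " failed: ", conditionMessage(err))
          FALSE
        })
      }
      dt <- proc.time()[["elapsed"]] - t0
      spl_log("info", sprintf("pair %s x %s: %s (%.2fs)", se$label,
                              fe$label,
                              if (cached) "cache hit" else "computed", dt))
      rows[[length(rows) + 1]] <- tibble::tibble(
        signal = se$label, feature = fe$label, signal_id = se$id,
        feature_id = fe$id, fingerprint = fp, computed = !cached,
        ok = ok, seconds = dt)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cache_dir") <- cache_dir
  attr(out, "anchor") <- anchor
  class(out) <- c("GridCache", class(out))
  out
}

#' Fetch one cached matrix
#'
#' @param coll a `Collection`
#' @param signal,feature entry ids or labels
#' @param anchor the [anchor_spec()] used at precompute time
#' @return a `ProfileMatrix`
#' @export
cached_matrix <- function(coll, signal, feature, anchor) {
  se <- collection_entry(coll, signal)
  fe <- collection_entry(coll, feature)
  fp <- pair_fingerprint(se$id, fe$id, anchor)
  m <- load_matrix_cache(file.path(coll$dir, "cache"), fp)
  if (is.null(m))
    stopf("no cached matrix for pair '%s' x '%s' under this anchor; run precompute()",
          se$label, fe$label)
  m
}

#' Batch-render profile plots or heatmaps for many pairs
#'
#' One PDF (plus JSON manifest) per requested combination, named
#' `"{signal}__{feature}__{kind}.pdf"`, in deterministic order. Every
#' pair must already be in the cache; a missing entry is an error naming
#' the pair.
#'
#' @param coll a `Collection`
#' @param pairs data frame with columns `signal` and `feature` (ids or
#'   labels), or `NULL` for the full cartesian grid of `signals` x
#'   `features`
#' @param anchor the [anchor_spec()] used at precompute time
#' @param kind `"profile"` or `"heatmap"`
#' @param out_dir output directory
#' @param spec a [plot_spec()]; defaults per kind
#' @param signals,features used when `pairs` is `NULL`
#' @param cluster optional `ClusterResult` applied to every heatmap
#' @return character vector of PDF paths written
#' @export
batch_render <- function(coll, pairs = NULL, anchor,
                         kind = c("profile", "heatmap"),
                         out_dir = ".", spec = NULL,
                         signals = NULL, features = NULL, cluster = NULL) {
  kind <- match.arg(kind)
  spec <- spec %||% plot_spec(kind)
  if (is.null(pairs)) {
    stopifnot(!is.null(signals), !is.null(features))
    pairs <- expand.grid(signal = signals, feature = features,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)[, c("signal", "feature")]
    pairs <- pairs[order(pairs$signal, pairs$feature), , drop = FALSE]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_len(nrow(pairs))) {
    m <- cached_matrix(coll, pairs$signal[i], pairs$feature[i], anchor)
    safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
    path <- file.path(out_dir, sprintf("%s__%s__%s.pdf",
                                       safe(m$signal_label),
                                       safe(m$feature_label), kind))
    if (kind == "profile") {
      plot_profile(summarize_profile(m), spec, path)
    } else {
      plot_heatmap(m, cluster %||% sort_rows(assemble_cluster_input(m)),
                   spec, path)
    }
    out <- c(out, path)
  }
  out
}
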