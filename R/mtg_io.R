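#' Read a multi-scale tree file
#'
#' Two dialects are supported.
#'
#' `"tabular"`: a CSV with one row per metamer and the interchange columns
#' `vertex_id, parent_id, edge_type, organ_type, year, top_x, top_y,
#' top_z, radius, length, leaf_area` (optional `has_fruit`, `gu`, and a
#' `scale_<name>` column giving the group id of a previously built scale,
#' which is re-inserted on read).
#'
#' `"amapmod"`: a documented subset of the classic AMAPmod/OpenAlea MTG
#' text format: a header with `CODE: FORM-A`, `CLASSES:` (one class
#' symbol per scale; exactly two coded scales, plant and metamer),
#' `DESCRIPTION:` and `FEATURES:` sections, then an `MTG:` section in
#' which each line carries one vertex as an absolute entity code
#' (`/P1/M1<M2+M3...`, `/` decomposition, `<` succession, `+` branching)
#' followed by tab-separated feature values.  Feature names are mapped to
#' the canonical property names through `property_map` (file name ->
#' canonical name), so files that encode growth-unit membership or shoot
#' year under other labels can be read without editing.  Anything outside
#' the subset is a parse error naming the line.  Coarser working scales
#' are not encoded in this dialect; they are rebuilt from properties with
#' [build_scale()].
#'
#' @param path file path.
#' @param dialect `"amapmod"` or `"tabular"`.
#' @param unit unit of lengths/coordinates in the file (`"m"`, `"cm"`,
#'   `"mm"`); everything is stored in metres.
#' @param property_map named character vector mapping file feature names
#'   to canonical property names (amapmod dialect).
#' @return a validated `mst`.
#' @export
read_mtg <- function(path, dialect = c("amapmod", "tabular"),
                     unit = "m", property_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tabular") .read_tabular(path, unit) else
    .read_amapmod(path, unit, property_map)
}

.read_tabular <- function(path, unit) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(vertex_id = "character",
                                       parent_id = "character"))
  scale_cols <- grep("^scale_", names(df), value = TRUE)
  tree <- mst_from_table(df[, setdiff(names(df), scale_cols), drop = FALSE],
                         unit = unit)
  if (length(scale_cols) > 1L) {
    stop("at most one built scale column is supported, found: ",
         paste(scale_cols, collapse = ", "))
  }
  if (length(scale_cols) == 1L) {
    sname <- sub("^scale_", "", scale_cols)
    lab <- stats::setNames(df[[scale_cols]], df$vertex_id)
    rule <- function(tr) {
      vs <- vertices_at(tr, finest_scale(tr))
      out <- lab[vs]
      names(out) <- vs
      out[is.na(out)] <- "root"
      out
    }
    tree <- build_scale(tree, scale_spec(sname, rule))
  }
  tree
}

#' Write a multi-scale tree file
#'
#' Inverse of [read_mtg()]: the tabular dialect writes one CSV row per
#' metamer (plus a `scale_<name>` column when the tree carries a built
#' scale); the amapmod dialect writes the documented MTG subset with the
#' canonical properties as features, including a `vid` feature preserving
#' the vertex ids so a read-back restores the identical graph.
#'
#' @param tree a validated `mst`.
#' @param path output file path.
#' @param dialect `"amapmod"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_mtg <- function(tree, path, dialect = c("amapmod", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") .write_tabular(tree, path) else
    .write_amapmod(tree, path)
  invisible(path)
}

.write_tabular <- function(tree, path) {
  vs <- vertices_at(tree, finest_scale(tree))
  df <- data.frame(
    vertex_id = vs,
    parent_id = tree$parent[vs],
    edge_type = tree$edge[vs],
    tree$props[vs, c("organ_type", "year", "top_x", "top_y", "top_z",
                     "radius", "length", "leaf_area", "has_fruit", "gu")],
    stringsAsFactors = FALSE
  )
  ns <- length(tree$scale_names)
  if (ns == 3L) {
    df[[paste0("scale_", tree$scale_names[2])]] <- tree$complex[vs]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

.amap_features <- c("organ_type", "year", "top_x", "top_y", "top_z",
                    "radius", "length", "leaf_area", "has_fruit", "gu",
                    "vid")
.amap_types <- c(organ_type = "ALPHA", year = "INT", top_x = "REAL",
                 top_y = "REAL", top_z = "REAL", radius = "REAL",
                 length = "REAL", leaf_area = "REAL", has_fruit = "INT",
                 gu = "ALPHA", vid = "ALPHA")

.write_amapmod <- function(tree, path) {
  if (length(tree$scale_names) != 2L) {
    stop("the amapmod dialect encodes base (plant, M) trees only; ",
         "use the tabular dialect for trees with a built scale")
  }
  vs <- vertices_at(tree, "M")
  root <- scale_root(tree, "M")
  idx <- stats::setNames(seq_along(vs), vs)   # M class indices
  code <- stats::setNames(character(length(vs)), vs)
  # preorder so every parent's code exists before its children
  has_par <- vs[!is.na(tree$parent[vs])]
  kids_of <- split(has_par, tree$parent[has_par])
  stack <- root
  order_out <- character(0)
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    order_out <- c(order_out, cur)
    p <- tree$parent[[cur]]
    code[cur] <- if (is.na(p)) {
      sprintf("/P1/M%d", idx[[cur]])
    } else {
      sprintf("%s%sM%d", code[[p]], tree$edge[[cur]], idx[[cur]])
    }
    stack <- c(sort(kids_of[[cur]]), stack)
  }
  lines <- c(
    "CODE:\tFORM-A",
    "CLASSES:",
    "SYMBOL\tSCALE\tDECOMPOSITION\tINDEXATION\tDEFINITION",
    "$\t0\tFREE\tFREE\tIMPLICIT",
    "P\t1\tFREE\tFREE\tEXPLICIT",
    "M\t2\tFREE\tFREE\tEXPLICIT",
    "DESCRIPTION:",
    "LEFT\tRIGHT\tRELTYPE\tMAX",
    "M\tM\t<\t?",
    "M\tM\t+\t?",
    "FEATURES:",
    "NAME\tTYPE",
    paste0(.amap_features, "\t", .amap_types[.amap_features]),
    "MTG:",
    paste(c("ENTITY-CODE", .amap_features), collapse = "\t"),
    paste0("/P1", paste(rep("\t", length(.amap_features)), collapse = ""))
  )
  num_fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  chr_fmt <- function(x) ifelse(is.na(x), "", x)
  body <- vapply(order_out, function(v) {
    p <- tree$props[v, ]
    paste(c(code[[v]], chr_fmt(p$organ_type), num_fmt(p$year),
            num_fmt(p$top_x), num_fmt(p$top_y), num_fmt(p$top_z),
            num_fmt(p$radius), num_fmt(p$length), num_fmt(p$leaf_area),
            num_fmt(p$has_fruit), chr_fmt(p$gu), v), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
}

.read_amapmod <- function(path, unit, property_map = NULL) {
  raw <- readLines(path)
  strip <- function(x) sub("\\s+$", "", x)
  raw <- strip(raw)
  sec <- function(name) {
    k <- grep(paste0("^", name, ":"), raw)
    if (!length(k)) stop("missing section '", name, ":' in ", path)
    k[1]
  }
  k_classes <- sec("CLASSES")
  k_features <- sec("FEATURES")
  k_mtg <- sec("MTG")
  k_desc <- grep("^DESCRIPTION:", raw)
  k_cls_end <- min(c(k_desc, k_features)[c(k_desc, k_features) > k_classes])
  # classes: symbol -> scale
  cls <- list()
  for (ln in (k_classes + 1):(k_cls_end - 1)) {
    line <- raw[ln]
    if (!nzchar(line) || grepl("^(SYMBOL|#)", line)) next
    parts <- strsplit(line, "\t")[[1]]
    if (length(parts) < 2) stop("line ", ln, ": malformed CLASSES entry")
    cls[[parts[1]]] <- as.integer(parts[2])
  }
  feat <- character(0)
  for (ln in (k_features + 1):(k_mtg - 1)) {
    line <- raw[ln]
    if (!nzchar(line) || grepl("^(NAME|#)", line)) next
    parts <- strsplit(line, "\t")[[1]]
    feat <- c(feat, parts[1])
  }
  if (!is.null(property_map)) {
    hit <- feat %in% names(property_map)
    feat[hit] <- property_map[feat[hit]]
  }
  body <- raw[(k_mtg + 1):length(raw)]
  body <- body[nzchar(gsub("\t", "", body))]
  if (length(body) && grepl("^ENTITY-CODE", body[1])) body <- body[-1]

  rows <- list()
  plant_seen <- FALSE
  for (bi in seq_along(body)) {
    line <- body[bi]
    lno <- k_mtg + 1 + bi
    parts <- strsplit(line, "\t")[[1]]
    codestr <- parts[1]
    vals <- parts[-1]
    if (!startsWith(codestr, "/")) {
      stop("line ", lno, ": entity code must be absolute (start with '/')")
    }
    toks <- regmatches(codestr,
                       gregexpr("[/<+]|[A-Za-z$][0-9]+", codestr))[[1]]
    # alternate symbol, entity, symbol, entity, ...
    ents <- list()
    k <- 1
    while (k <= length(toks)) {
      sym <- toks[k]
      if (!sym %in% c("/", "<", "+")) {
        stop("line ", lno, ": expected edge symbol, got '", sym, "'")
      }
      ent <- toks[k + 1]
      if (is.na(ent)) stop("line ", lno, ": dangling edge symbol")
      klass <- substr(ent, 1, 1)
      if (is.null(cls[[klass]])) {
        stop("line ", lno, ": unknown class '", klass, "'")
      }
      ents[[length(ents) + 1L]] <- list(sym = sym, ent = ent,
                                        scale = cls[[klass]])
      k <- k + 2
    }
    last <- ents[[length(ents)]]
    if (last$scale == 1L) { plant_seen <- TRUE; next }
    if (last$scale != 2L) {
      stop("line ", lno, ": this dialect subset codes scales 1 and 2 only")
    }
    if (length(ents) < 2) stop("line ", lno, ": metamer without a plant")
    prev <- ents[[length(ents) - 1L]]
    parent <- if (prev$scale == 1L) NA_character_ else prev$ent
    edge <- if (last$sym == "/") NA_character_ else last$sym
    if (!is.na(parent) && last$sym == "/") {
      stop("line ", lno, ": '/' inside the metamer scale")
    }
    fv <- stats::setNames(rep(NA_character_, length(feat)), feat)
    fv[seq_along(vals)] <- vals
    fv[fv == ""] <- NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      code_id = last$ent, parent_code = parent, edge_type = edge,
      t(fv), stringsAsFactors = FALSE)
  }
  if (!plant_seen) stop("no plant-scale vertex in ", path)
  if (!length(rows)) stop("no metamer-scale vertices in ", path)
  df <- do.call(rbind, rows)
  num <- function(x) suppressWarnings(as.numeric(x))
  vid <- if ("vid" %in% names(df) && !anyNA(df$vid)) df$vid else df$code_id
  remap <- stats::setNames(vid, df$code_id)
  out <- data.frame(
    vertex_id = vid,
    parent_id = ifelse(is.na(df$parent_code), NA_character_,
                       remap[df$parent_code]),
    edge_type = df$edge_type,
    organ_type = if ("organ_type" %in% names(df)) df$organ_type else NA,
    year = if ("year" %in% names(df)) num(df$year) else NA_real_,
    top_x = num(df$top_x), top_y = num(df$top_y), top_z = num(df$top_z),
    radius = if ("radius" %in% names(df)) num(df$radius) else 0,
    length = num(df$length),
    leaf_area = if ("leaf_area" %in% names(df)) num(df$leaf_area) else 0,
    has_fruit = if ("has_fruit" %in% names(df)) num(df$has_fruit) else 0,
    gu = if ("gu" %in% names(df)) df$gu else NA_character_,
    stringsAsFactors = FALSE
  )
  mst_from_table(out, unit = unit)
}

#' Dump a validated tree as JSON
#'
#' Writes the full graph (vertices, scales, parents, edges, complexes,
#' properties, scale names) as a single JSON object.
#'
#' @param tree a validated `mst`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
mst_to_json <- function(tree, path) {
  obj <- list(
    scale_names = tree$scale_names,
    vertices = data.frame(
      vertex = tree$vertex,
      scale = unname(tree$scale[tree$vertex]),
      parent = unname(tree$parent[tree$vertex]),
      edge = unname(tree$edge[tree$vertex]),
      complex = unname(tree$complex[tree$vertex]),
      tree$props[tree$vertex, ],
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
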