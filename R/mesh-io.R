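# Mesh file I/O: legacy VTK polydata, VTP (XML, ascii), PLY (ascii + binary
# little-endian), STL (ascii + binary, vertex-welded), OBJ.
#
# Per-vertex fields travel as named point-data arrays where the format allows
# (VTK/VTP, PLY vertex properties). The ostium ring and landmark are encoded
# as integer point arrays `ostium_ring_order` (-1 = not on ring, else 0-based
# ring position) and `landmark` (1 at the landmark vertex), and decoded back
# on read. All indices in files are 0-based.

fmt_num <- function(x) sprintf("%.17g", x)

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("vtk", "vtp", "ply", "stl", "obj")) ext
  else stop("cannot infer mesh format from extension: ", path)
}

#' Read a triangle surface mesh
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"vtk"}, \code{"vtp"},
#'   \code{"ply"}, \code{"stl"}, \code{"obj"}.
#' @return a \code{surface_mesh}. STL input is vertex-welded on exact
#'   coordinate match. The point arrays \code{ostium_ring_order} and
#'   \code{landmark}, when present, populate the mesh's ostium ring and
#'   landmark instead of appearing as fields.
#' @export
read_mesh <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  raw <- switch(format,
                vtk = read_vtk_legacy(path),
                vtp = read_vtp(path),
                ply = read_ply(path),
                stl = read_stl(path),
                obj = read_obj(path),
                stop("unsupported mesh format: ", format))
  fields <- raw$fields %||% list()
  ring <- NULL; landmark <- NULL
  if (!is.null(fields$ostium_ring_order)) {
    ord <- round(fields$ostium_ring_order)
    on_ring <- which(ord >= 0)
    ring <- on_ring[order(ord[on_ring])]
    fields$ostium_ring_order <- NULL
  }
  if (!is.null(fields$landmark)) {
    lm <- which(round(fields$landmark) == 1)
    if (length(lm)) landmark <- lm[1]
    fields$landmark <- NULL
  }
  surface_mesh(raw$vertices, raw$faces, fields = fields,
               ostium_ring = ring, landmark = landmark)
}

#' Write a triangle surface mesh
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output path; the extension selects the format unless
#'   \code{format} is given.
#' @param format one of \code{"auto"}, \code{"vtk"}, \code{"vtp"},
#'   \code{"ply"}, \code{"stl"}, \code{"obj"}.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto") {
  if (format == "auto") format <- guess_format(path)
  fields <- mesh$fields %||% list()
  V <- nrow(mesh$vertices)
  if (!is.null(mesh$ostium_ring)) {
    ord <- rep(-1, V)
    ord[mesh$ostium_ring] <- seq_along(mesh$ostium_ring) - 1
    fields$ostium_ring_order <- ord
  }
  if (!is.null(mesh$landmark)) {
    lm <- rep(0, V); lm[mesh$landmark] <- 1
    fields$landmark <- lm
  }
  switch(format,
         vtk = write_vtk_legacy(mesh, fields, path),
         vtp = write_vtp(mesh, fields, path),
         ply = write_ply(mesh, fields, path),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_nums <- function(x) as.numeric(strsplit(trimws(paste(x, collapse = " ")),
                                              "[[:space:]]+")[[1]])

# ---- legacy VTK ------------------------------------------------------------

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("ASCII", toupper(lines[3])))
    stop("only ASCII legacy VTK files are supported: ", path)
  i <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i], "[[:space:]]+")[[1]][2])
  toks <- numeric(0); j <- i + 1
  while (length(toks) < 3 * n) {
    toks <- c(toks, split_nums(lines[j])); j <- j + 1
  }
  verts <- matrix(toks[1:(3 * n)], ncol = 3, byrow = TRUE)
  ip <- grep("^POLYGONS", lines)
  if (!length(ip)) stop("no POLYGONS section in ", path)
  hdr <- as.integer(strsplit(lines[ip[1]], "[[:space:]]+")[[1]][2:3])
  nf <- hdr[1]
  toks <- numeric(0); j <- ip[1] + 1
  while (length(toks) < hdr[2]) {
    toks <- c(toks, split_nums(lines[j])); j <- j + 1
  }
  faces <- matrix(NA_integer_, nf, 3); pos <- 1
  for (k in seq_len(nf)) {
    m <- toks[pos]
    if (m != 3) stop("unsupported-topology: face ", k, " is a ",
                     if (m == 4) "quad" else paste0(m, "-gon"),
                     "; only triangles are supported")
    faces[k, ] <- toks[(pos + 1):(pos + 3)] + 1L
    pos <- pos + m + 1
  }
  fields <- list()
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd)) {
    j <- ipd[1] + 1
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (grepl("^SCALARS", ln)) {
        nm <- strsplit(ln, "[[:space:]]+")[[1]][2]
        j <- j + 2  # skip LOOKUP_TABLE
        toks <- numeric(0)
        while (length(toks) < n) { toks <- c(toks, split_nums(lines[j])); j <- j + 1 }
        fields[[nm]] <- toks[1:n]
      } else if (grepl("^VECTORS", ln)) {
        nm <- strsplit(ln, "[[:space:]]+")[[1]][2]
        j <- j + 1
        toks <- numeric(0)
        while (length(toks) < 3 * n) { toks <- c(toks, split_nums(lines[j])); j <- j + 1 }
        fields[[nm]] <- matrix(toks[1:(3 * n)], ncol = 3, byrow = TRUE)
      } else if (nchar(ln) == 0) j <- j + 1 else break
    }
  }
  list(vertices = verts, faces = faces, fields = fields)
}

write_vtk_legacy <- function(mesh, fields, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(apply(f, 1, function(r) paste(c(3, r - 1L), collapse = " ")), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(fields)) {
      val <- fields[[nm]]
      if (is.matrix(val) && ncol(val) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(val, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(fmt_num(as.vector(val)), con)
      }
    }
  }
}

# ---- VTP (XML PolyData, ascii) --------------------------------------------

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  n <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  pts_da <- xml2::xml_find_first(piece, "./Points/DataArray")
  verts <- matrix(split_nums(xml2::xml_text(pts_da))[1:(3 * n)],
                  ncol = 3, byrow = TRUE)
  conn <- split_nums(xml2::xml_text(xml2::xml_find_first(
    piece, "./Polys/DataArray[@Name='connectivity']")))
  offs <- split_nums(xml2::xml_text(xml2::xml_find_first(
    piece, "./Polys/DataArray[@Name='offsets']")))
  sizes <- diff(c(0, offs))
  if (any(sizes != 3)) {
    m <- sizes[sizes != 3][1]
    stop("unsupported-topology: polygon with ", m, " vertices (",
         if (m == 4) "quad" else "poly", "); only triangles are supported")
  }
  faces <- matrix(as.integer(conn) + 1L, ncol = 3, byrow = TRUE)
  fields <- list()
  for (da in xml2::xml_find_all(piece, "./PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    nc <- as.integer(xml2::xml_attr(da, "NumberOfComponents") %||% "1")
    if (is.na(nc)) nc <- 1L
    vals <- split_nums(xml2::xml_text(da))
    fields[[nm]] <- if (nc == 1) vals[1:n] else
      matrix(vals[1:(nc * n)], ncol = nc, byrow = TRUE)
  }
  list(vertices = verts, faces = faces, fields = fields)
}

write_vtp <- function(mesh, fields, path) {
  v <- mesh$vertices; f <- mesh$faces
  da <- function(name, ncomp, type, body)
    sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            type, name, ncomp, body)
  pts <- paste(apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")),
               collapse = "\n")
  conn <- paste(as.vector(t(f - 1L)), collapse = " ")
  offs <- paste(seq_len(nrow(f)) * 3L, collapse = " ")
  pd <- ""
  if (length(fields)) {
    parts <- vapply(names(fields), function(nm) {
      val <- fields[[nm]]
      if (is.matrix(val))
        da(nm, ncol(val), "Float64",
           paste(apply(val, 1, function(r) paste(fmt_num(r), collapse = " ")),
                 collapse = "\n"))
      else da(nm, 1L, "Float64", paste(fmt_num(as.vector(val)), collapse = "\n"))
    }, character(1))
    pd <- sprintf("<PointData>\n%s\n</PointData>", paste(parts, collapse = "\n"))
  }
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">
<PolyData>
<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">
<Points>
%s
</Points>
%s
<Polys>
%s
%s
</Polys>
</Piece>
</PolyData>
</VTKFile>', nrow(v), nrow(f),
    da("Points", 3L, "Float64", pts), pd,
    da("connectivity", 1L, "Int64", conn),
    da("offsets", 1L, "Int64", offs))
  writeLines(xml, path)
}

# ---- PLY -------------------------------------------------------------------

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("unexpected end of PLY header")
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt <- strsplit(grep("^format", hdr, value = TRUE)[1], "[[:space:]]+")[[1]][2]
  elems <- list(); cur <- NULL
  for (ln in hdr) {
    t <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (t[1] == "element") {
      cur <- t[2]
      elems[[cur]] <- list(n = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <-
        if (t[2] == "list") list(list = TRUE, count_type = t[3],
                                 item_type = t[4], name = t[5])
        else list(list = FALSE, type = t[2], name = t[3])
    }
  }
  ve <- elems[["vertex"]]; fe <- elems[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY without vertex/face elements")
  vp_names <- vapply(ve$props, `[[`, character(1), "name")
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    vlines <- txt[seq_len(ve$n)]
    flines <- txt[ve$n + seq_len(fe$n)]
    vdat <- matrix(unlist(lapply(vlines, split_nums)), nrow = ve$n, byrow = TRUE)
    faces <- matrix(NA_integer_, fe$n, 3)
    for (k in seq_len(fe$n)) {
      nums <- split_nums(flines[k])
      m <- nums[1]
      if (m != 3) stop("unsupported-topology: face ", k, " is a ",
                       if (m == 4) "quad" else paste0(m, "-gon"))
      faces[k, ] <- nums[2:4] + 1L
    }
  } else if (fmt == "binary_little_endian") {
    read_scalar <- function(type) {
      sz <- ply_type_size[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "double", 1, size = sz, endian = "little")
      else readBin(con, "integer", 1, size = sz, endian = "little",
                   signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    vdat <- matrix(0, ve$n, length(ve$props))
    for (r in seq_len(ve$n))
      for (c in seq_along(ve$props))
        vdat[r, c] <- read_scalar(ve$props[[c]]$type)
    faces <- matrix(NA_integer_, fe$n, 3)
    lp <- fe$props[[1]]
    for (r in seq_len(fe$n)) {
      m <- read_scalar(lp$count_type)
      if (m != 3) stop("unsupported-topology: face ", r, " is a ",
                       if (m == 4) "quad" else paste0(m, "-gon"))
      faces[r, ] <- vapply(1:3, function(i) read_scalar(lp$item_type),
                           numeric(1)) + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  xyz <- match(c("x", "y", "z"), vp_names)
  if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z")
  verts <- vdat[, xyz, drop = FALSE]
  fields <- list()
  extra <- setdiff(seq_along(vp_names), xyz)
  for (c in extra) fields[[vp_names[c]]] <- vdat[, c]
  list(vertices = verts, faces = faces, fields = fields)
}

write_ply <- function(mesh, fields, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  scalar_fields <- fields[!vapply(fields, is.matrix, logical(1))]
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("property double %s", names(scalar_fields)),
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vdat <- cbind(v, do.call(cbind, c(lapply(scalar_fields, as.vector),
                                    list(deparse.level = 0))))
  writeLines(apply(vdat, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(apply(f, 1, function(r) paste(c(3, r - 1L), collapse = " ")), con)
}

# ---- STL -------------------------------------------------------------------

read_stl <- function(path) {
  # sniff ascii vs binary
  head_bytes <- readBin(path, "raw", 512)
  txt_head <- suppressWarnings(rawToChar(head_bytes[head_bytes != as.raw(0)]))
  is_ascii <- grepl("^\\s*solid", txt_head, useBytes = TRUE) &&
    grepl("facet", txt_head, fixed = TRUE, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    tri <- t(vapply(vl, function(ln) split_nums(sub("^\\s*vertex", "", ln)),
                    numeric(3), USE.NAMES = FALSE))
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(0, 3 * nf, 3)
    for (k in seq_len(nf)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      tri[(3 * k - 2):(3 * k), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  }
  if (nrow(tri) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- apply(tri, 1, function(r) paste(fmt_num(r), collapse = "_"))
  uk <- unique(key)
  vid <- match(key, uk)
  verts <- tri[match(uk, key), , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces, fields = list())
}

write_stl <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  fn <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  writeLines("solid mesh", con)
  for (k in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %s", paste(fmt_num(fn[k, ]), collapse = " ")),
                 "    outer loop",
                 sprintf("      vertex %s",
                         apply(v[f[k, ], , drop = FALSE], 1,
                               function(r) paste(fmt_num(r), collapse = " "))),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

# ---- OBJ -------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- t(vapply(vl, function(ln) split_nums(sub("^v", "", ln))[1:3],
                    numeric(3), USE.NAMES = FALSE))
  faces <- matrix(NA_integer_, length(fl), 3)
  for (k in seq_along(fl)) {
    toks <- strsplit(trimws(sub("^f", "", fl[k])), "[[:space:]]+")[[1]]
    if (length(toks) != 3)
      stop("unsupported-topology: face ", k, " is a ",
           if (length(toks) == 4) "quad" else paste0(length(toks), "-gon"))
    faces[k, ] <- as.integer(vapply(strsplit(toks, "/"), `[[`, character(1), 1))
  }
  list(vertices = verts, faces = faces, fields = list())
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(apply(mesh$vertices, 1,
                   function(r) paste(c("v", fmt_num(r)), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1,
                   function(r) paste(c("f", r), collapse = " ")), con)
}
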