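# Standard-format I/O: BEDPE junctions, BED-like copy-number segments,
# progeny tally TSVs, YAML configuration and JSON sidecars.

.bedpeHeader <- paste0(
  "# BEDPE junctions; 0-based half-open breakend intervals; ",
  "strand '+' = retained sequence at coordinates <= pos (side R), ",
  "strand '-' = retained sequence at coordinates >= pos (side L)")

#' Write junctions to a 10-column BEDPE file
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score strand1
#' strand2.  Breakends are written as 1 bp intervals `[pos, pos + 1)`;
#' side `R` maps to strand `"+"`, side `L` to `"-"`; the untemplated
#' insert length is stored in the score column.  A header comment
#' documents the convention.
#'
#' @param junctions A [JunctionSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedpe <- function(junctions, path) {
  stopifnot(is(junctions, "JunctionSet"))
  j <- junctions@junctions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.bedpeHeader, con)
  if (nrow(j)) {
    df <- data.frame(j$chromA, j$posA, j$posA + 1,
                     j$chromB, j$posB, j$posB + 1,
                     name = sprintf("junction_%d", seq_len(nrow(j))),
                     score = j$insertLen,
                     strand1 = ifelse(j$sideA == "R", "+", "-"),
                     strand2 = ifelse(j$sideB == "R", "+", "-"))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read junctions from a 10-column BEDPE file
#'
#' Inverse of [writeBedpe()]: a written junction set reads back
#' identically.  Malformed lines and strands other than `"+"`/`"-"` are
#' rejected with the offending line number.
#'
#' @param path BEDPE file path.
#' @return A [JunctionSet-class].
#' @export
readBedpe <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(JunctionSet())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 10L)
      stop(sprintf("line %d: expected 10 BEDPE columns, found %d",
                   lineNo[i], length(f)))
    s1 <- f[9L]; s2 <- f[10L]
    if (!s1 %in% c("+", "-") || !s2 %in% c("+", "-"))
      stop(sprintf("line %d: strand must be '+' or '-', found '%s'/'%s'",
                   lineNo[i], s1, s2))
    p1 <- suppressWarnings(as.numeric(f[2L]))
    p2 <- suppressWarnings(as.numeric(f[5L]))
    score <- suppressWarnings(as.numeric(f[8L]))
    if (is.na(p1) || is.na(p2))
      stop(sprintf("line %d: non-numeric breakend coordinates", lineNo[i]))
    data.frame(chromA = f[1L], posA = p1,
               sideA = if (s1 == "+") "R" else "L",
               chromB = f[4L], posB = p2,
               sideB = if (s2 == "+") "R" else "L",
               insertLen = if (is.na(score)) 0 else score,
               stringsAsFactors = FALSE)
  })
  JunctionSet(do.call(rbind, rows))
}

#' Write a copy-number profile as 4-column BED
#'
#' Columns: chrom, start, end, cn (0-based half-open).
#'
#' @param cn A [CNProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCnBed <- function(cn, path) {
  stopifnot(is(cn, "CNProfile"))
  df <- data.frame(cn@chrom, format(cn@segments$start, scientific = FALSE,
                                    trim = TRUE),
                   format(cn@segments$end, scientific = FALSE, trim = TRUE),
                   cn@segments$cn)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a copy-number profile from 4-column BED
#'
#' Validates that the segments tile the chromosome contiguously; gaps or
#' overlaps are rejected listing the offending intervals.
#'
#' @param path BED file path (chrom, start, end, cn).
#' @return A [CNProfile-class].
#' @export
readCnBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "cn"),
                   stringsAsFactors = FALSE)
  if (length(unique(df$chrom)) != 1L)
    stop("copy-number BED must describe a single chromosome")
  df <- df[order(df$start), ]
  bad <- which(df$start[-1L] != df$end[-nrow(df)])
  if (length(bad))
    stop("copy-number segments do not tile contiguously at: ",
         paste(sprintf("[%g,%g)/[%g,%g)", df$start[bad], df$end[bad],
                       df$start[bad + 1L], df$end[bad + 1L]),
               collapse = ", "))
  if (df$start[1L] != 0)
    stop("copy-number profile must start at 0")
  if (any(df$cn < 0)) stop("negative copy number")
  CNProfile(df[, c("start", "end", "cn")], length = df$end[nrow(df)],
            chrom = df$chrom[1L])
}

#' Read or write a progeny tally TSV
#'
#' Two tab-separated columns: phenotype label and non-negative integer
#' count.
#'
#' @param path File path.
#' @return `readProgenyTsv`: named integer vector of counts.
#' @export
readProgenyTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("phenotype", "count"),
                   stringsAsFactors = FALSE, quote = "")
  if (any(is.na(df$count)) || any(df$count < 0) ||
      any(df$count != round(df$count)))
    stop("tally counts must be non-negative integers")
  setNames(as.integer(df$count), df$phenotype)
}

#' @rdname readProgenyTsv
#' @param tally Named integer vector of phenotype counts.
#' @return `writeProgenyTsv`: `path`, invisibly.
#' @export
writeProgenyTsv <- function(tally, path) {
  write.table(data.frame(names(tally), as.integer(tally)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a simulation profile from a YAML file
#'
#' The file may set any subset of the profile fields (see
#' [cloneProfile()]); unset fields fall back to the defaults of the base
#' profile named by its `base` key (default `"rtel1_null"` when the file
#' defines complex-event parameters, else `"wild_type"`).
#'
#' @param path YAML file path.
#' @return A profile list for [simulateClone()].
#' @export
readProfile <- function(path) {
  y <- yaml::read_yaml(path)
  baseName <- y$base
  if (is.null(baseName))
    baseName <- if (any(c("templatedInsertion", "bfb", "chromothripsis")
                        %in% names(y))) "rtel1_null" else "wild_type"
  prof <- cloneProfile(baseName)
  y$base <- NULL
  for (k in names(y)) {
    if (is.list(prof[[k]]) && is.list(y[[k]]))
      prof[[k]] <- utils::modifyList(prof[[k]], y[[k]])
    else prof[[k]] <- y[[k]]
  }
  if (!is.null(y$classProbs)) prof$classProbs <- unlist(y$classProbs)
  prof
}

#' Read a cross design from a YAML file
#'
#' Expected keys: `markers` (list of records with `name`, `dominance`,
#' `haplotype`, `side`) and optional `viability` (genotype to value map).
#'
#' @param path YAML file path.
#' @return A [CrossDesign-class].
#' @export
readCrossDesign <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers)) stop("cross design YAML needs a 'markers' key")
  mk <- do.call(rbind, lapply(y$markers, function(m)
    data.frame(name = m$name, dominance = m$dominance,
               haplotype = m$haplotype, side = m$side,
               stringsAsFactors = FALSE)))
  CrossDesign(mk, viability = if (!is.null(y$viability))
    unlist(y$viability) else NULL)
}

#' Write ground-truth event records as a JSON sidecar
#'
#' @param events Event list as returned in `simulateClone()$events`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEventRecords <- function(events, path) {
  jsonlite::write_json(lapply(events, function(e) {
    e$params <- unclass(e$params)
    e
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the seed, configuration and package version needed to
#' reproduce a run of the deterministic pipeline stages.
#'
#' @param path Output path.
#' @param seed Integer seed used.
#' @param config Arbitrary configuration list.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, seed, config = list()) {
  jsonlite::write_json(list(
    package = "htrec",
    version = as.character(packageVersion("htrec")),
    rVersion = R.version.string,
    seed = seed,
    config = config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
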