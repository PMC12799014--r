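#' Read and write stock tables as long-format CSV
#'
#' The interchange schema has one row per stock-year-age with columns
#' \code{stock_id, species, region, year, age, abundance_n, catch_n,
#' weight_kg, maturity_prop, m_annual}. \code{readStockTable} validates
#' hard: a missing column, a negative value, catch exceeding abundance, or
#' non-contiguous years each raise an error naming the offending rows.
#'
#' @param path CSV file path.
#' @return \code{readStockTable}: a [StockTable-class] (the file must
#'   contain exactly one stock); \code{readStockTables}: a named list of
#'   [StockTable-class], one per stock in the file.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeStockTable(makeStationaryFixture(), tf)
#' st <- readStockTable(tf)
#' @export
readStockTable <- function(path) {
  tables <- readStockTables(path)
  if (length(tables) != 1L)
    stop(sprintf("'%s' contains %d stocks; use readStockTables()", path,
                 length(tables)), call. = FALSE)
  tables[[1]]
}

#' @rdname readStockTable
#' @export
readStockTables <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stock_id", "species", "region", "year", "age", "abundance_n",
            "catch_n", "weight_kg", "maturity_prop", "m_annual")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in c("abundance_n", "catch_n")) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative %s at row(s) %s of '%s'", col,
                   paste(utils::head(bad, 5), collapse = ", "), path),
           call. = FALSE)
  }
  bad <- which(df$catch_n > df$abundance_n)
  if (length(bad))
    stop(sprintf("catch exceeds abundance at row(s) %s of '%s' (year %s, age %s)",
                 paste(utils::head(bad, 5), collapse = ", "), path,
                 df$year[bad[1]], df$age[bad[1]]), call. = FALSE)
  out <- lapply(split(df, df$stock_id), function(d) {
    yrs <- sort(unique(d$year))
    agevec <- sort(unique(d$age))
    if (length(yrs) > 1 && any(diff(yrs) != 1))
      stop(sprintf("stock '%s': years are not contiguous (%s)", d$stock_id[1],
                   paste(yrs, collapse = ", ")), call. = FALSE)
    if (length(agevec) > 1 && any(diff(agevec) != 1))
      stop(sprintf("stock '%s': ages are not contiguous", d$stock_id[1]),
           call. = FALSE)
    if (nrow(d) != length(yrs) * length(agevec))
      stop(sprintf("stock '%s': incomplete year x age grid", d$stock_id[1]),
           call. = FALSE)
    grab <- function(col) {
      mat <- matrix(NA_real_, length(yrs), length(agevec))
      mat[cbind(match(d$year, yrs), match(d$age, agevec))] <- d[[col]]
      mat
    }
    StockTable(stockId = d$stock_id[1], species = d$species[1],
               region = d$region[1], years = yrs, ages = agevec,
               N = grab("abundance_n"), C = grab("catch_n"),
               W = grab("weight_kg"), Mat = grab("maturity_prop"),
               M = grab("m_annual"))
  })
  out
}

#' @rdname readStockTable
#' @param stock a [StockTable-class] to serialize.
#' @export
writeStockTable <- function(stock, path) {
  utils::write.csv(as.data.frame(stock), path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a key-value text file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment; vector
#' values are comma-separated. Keys use the CSV schema's snake_case
#' (\code{n_years, first_age, max_age, recruits_per_kg_mean,
#' recruitment_cv, large_event_prob, large_event_multiplier, m_at_age,
#' f_selectivity, weight_at_age, maturity_at_age, initial_abundance,
#' seed}); unspecified keys keep the [SimConfig()] defaults.
#'
#' @param path text file path.
#' @return a [SimConfig()].
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  keymap <- c(n_years = "nYears", first_age = "firstAge", max_age = "maxAge",
              recruits_per_kg_mean = "recruitsPerKgMean",
              recruitment_cv = "recruitmentCv",
              large_event_prob = "largeEventProb",
              large_event_multiplier = "largeEventMultiplier",
              m_at_age = "mAtAge", f_selectivity = "fSelectivity",
              weight_at_age = "weightAtAge", maturity_at_age = "maturityAtAge",
              initial_abundance = "initialAbundance", seed = "seed")
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% names(keymap))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    vals <- as.numeric(strsplit(trimws(kv[2]), ",", fixed = TRUE)[[1]])
    if (anyNA(vals))
      stop(sprintf("non-numeric value for config key '%s'", key), call. = FALSE)
    args[[keymap[[key]]]] <- vals
  }
  do.call(SimConfig, args)
}
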