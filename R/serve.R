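#' Serve a bundle over local HTTP
#'
#' Starts a background static web server rooted at `bundle_dir`, so the
#' bundle's files can be read by a browser (static serving is required for a
#' page to read locally stored data files). The server handles plain `GET`
#' requests only. If the requested port is busy, the next free port (scanning
#' upward) is used and a warning is emitted; the chosen port is reported in
#' the returned handle.
#'
#' @param bundle_dir directory to serve (e.g. a [assemble_site()] output).
#' @param port requested TCP port (default 8080).
#' @return A `tract_server` handle with elements `port`, `url`, `dir` and the
#'   background `process`; stop it with [stop_server()].
#' @export
serve_site <- function(bundle_dir, port = 8080L) {
  if (!dir.exists(bundle_dir)) {
    stop_tract("bundle directory %s does not exist", bundle_dir)
  }
  stopifnot(is_count(port))
  portfile <- tempfile(fileext = ".port")
  proc <- callr::r_bg(
    function(dir, port, portfile) {
      tractometry:::serve_loop(dir, port, portfile)
    },
    args = list(dir = normalizePath(bundle_dir), port = as.integer(port),
                portfile = portfile),
    package = TRUE, supervise = TRUE)
  deadline <- Sys.time() + 15
  while (!file.exists(portfile) && proc$is_alive() && Sys.time() < deadline) {
    Sys.sleep(0.05)
  }
  if (!file.exists(portfile)) {
    err <- tryCatch(proc$read_all_error(), error = function(e) "")
    proc$kill()
    stop_tract("server failed to start%s",
               if (nzchar(err)) paste0(": ", err) else "")
  }
  chosen <- as.integer(readLines(portfile, n = 1L))
  if (chosen != port) {
    warn_tract("port %d busy; serving on %d instead", port, chosen)
  }
  structure(
    list(port = chosen, url = sprintf("http://localhost:%d/", chosen),
         dir = normalizePath(bundle_dir), process = proc),
    class = "tract_server")
}

#' @rdname serve_site
#' @param server a `tract_server` handle.
#' @export
stop_server <- function(server) {
  stopifnot(inherits(server, "tract_server"))
  if (server$process$is_alive()) server$process$kill()
  invisible(server)
}

#' @export
print.tract_server <- function(x, ...) {
  cat(sprintf("<tract_server> %s serving %s (%s)\n", x$url, x$dir,
              if (x$process$is_alive()) "running" else "stopped"))
  invisible(x)
}

# Blocking accept-respond loop run in the background process. Writes the
# chosen port to `portfile` once listening.
serve_loop <- function(dir, port, portfile) {
  srv <- NULL
  chosen <- NA_integer_
  for (p in port:(port + 100L)) {
    srv <- tryCatch(serverSocket(p), error = function(e) NULL)
    if (!is.null(srv)) { chosen <- p; break }
  }
  if (is.null(srv)) stop("no free port found")
  on.exit(close(srv))
  writeLines(as.character(chosen), portfile)
  repeat {
    con <- tryCatch(
      socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 3600),
      error = function(e) NULL)
    if (is.null(con)) next
    tryCatch(serve_one(con, dir), error = function(e) NULL)
    tryCatch(close(con), error = function(e) NULL)
  }
}

serve_one <- function(con, dir) {
  req <- readLines(con, n = 1L)
  if (!length(req)) return(invisible())
  # drain headers
  repeat {
    h <- readLines(con, n = 1L)
    if (!length(h) || !nzchar(h)) break
  }
  m <- regmatches(req, regexec("^GET[ ]+([^ ]+)", req))[[1]]
  if (length(m) != 2L) {
    return(http_respond(con, 400L, "Bad Request",
                        charToRaw("bad request\n")))
  }
  path <- sub("[?#].*$", "", m[2])
  path <- tryCatch(percent_decode(path), error = function(e) NULL)
  if (is.null(path) || grepl("\\.\\.", path)) {
    return(http_respond(con, 404L, "Not Found", charToRaw("not found\n")))
  }
  if (endsWith(path, "/")) path <- paste0(path, "index.html")
  target <- file.path(dir, sub("^/+", "", path))
  if (!file.exists(target) || dir.exists(target)) {
    return(http_respond(con, 404L, "Not Found", charToRaw("not found\n")))
  }
  body <- readBin(target, "raw", n = file.info(target)$size)
  http_respond(con, 200L, "OK", body, content_type_of(target))
}

http_respond <- function(con, code, reason, body,
                         ctype = "text/plain; charset=utf-8") {
  head <- sprintf(
    "HTTP/1.0 %d %s\r\nContent-Type: %s\r\nContent-Length: %d\r\nConnection: close\r\n\r\n",
    code, reason, ctype, length(body))
  writeBin(c(charToRaw(head), body), con)
  flush(con)
  invisible()
}

content_type_of <- function(path) {
  switch(tolower(tools::file_ext(path)),
         html = "text/html; charset=utf-8",
         css = "text/css",
         js = "application/javascript",
         json = "application/json",
         csv = "text/csv; charset=utf-8",
         "application/octet-stream")
}

# Minimal HTTP GET used in examples/tests; returns list(status, body raw).
http_fetch <- function(port, path, host = "127.0.0.1") {
  con <- socketConnection(host, port, blocking = TRUE, open = "r+b",
                          timeout = 10)
  on.exit(close(con))
  writeBin(charToRaw(sprintf("GET %s HTTP/1.0\r\nHost: %s\r\n\r\n",
                             path, host)), con)
  flush(con)
  status_line <- readLines(con, n = 1L)
  status <- as.integer(sub("^HTTP/[0-9.]+ ([0-9]+).*$", "\\1", status_line))
  clen <- NA_integer_
  repeat {
    h <- readLines(con, n = 1L)
    if (!length(h) || !nzchar(h)) break
    if (grepl("^Content-Length:", h, ignore.case = TRUE)) {
      clen <- as.integer(trimws(sub("^[^:]+:", "", h)))
    }
  }
  body <- if (!is.na(clen)) readBin(con, "raw", n = clen) else raw(0)
  list(status = status, body = body)
}
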