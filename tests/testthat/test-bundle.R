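site_fixture <- function(seed = 41, dir = tempfile()) {
  ds <- generate_dataset(synthetic_spec(n_subjects = 4, seed = seed,
                                        n_nodes = 12,
                                        tract_names = c("Left CST",
                                                        "Right CST"),
                                        metric_names = c("fa", "md")))
  list(ds = ds, bundle = assemble_site(ds, dir), dir = dir)
}

test_that("an assembled site has the contracted layout and a complete manifest", {
  fx <- site_fixture()
  root <- fx$bundle$root
  for (f in c("data/nodes.csv", "data/subjects.csv", "data/subjects.json",
              "data/params.json", "manifest.json", "index.html")) {
    expect_true(file.exists(file.path(root, f)), label = f)
  }
  # walking the bundle finds exactly the manifest's files
  on_disk <- sort(setdiff(list.files(root, recursive = TRUE),
                          "manifest.json"))
  expect_identical(sort(fx$bundle$manifest$path), on_disk)
  # hashes verify
  expect_s3_class(read_site_bundle(root), "site_bundle")
})

test_that("re-assembly of an unchanged dataset reproduces identical hashes", {
  fx <- site_fixture(seed = 42)
  b2 <- assemble_site(fx$ds, tempfile())
  m1 <- fx$bundle$manifest; m2 <- b2$manifest
  expect_identical(m1$path, m2$path)
  expect_identical(m1$sha256, m2$sha256)
})

test_that("editing one metadata cell changes exactly the subjects.* files", {
  fx <- site_fixture(seed = 43)
  ds2 <- fx$ds
  ds2$metadata$age[2] <- ds2$metadata$age[2] + 1
  b2 <- assemble_site(ds2, tempfile())
  m1 <- fx$bundle$manifest; m2 <- b2$manifest
  changed <- m1$path[m1$sha256 != m2$sha256[match(m1$path, m2$path)]]
  expect_setequal(changed, c("data/subjects.csv", "data/subjects.json"))
})

test_that("a non-empty outdir is refused without overwrite", {
  fx <- site_fixture(seed = 44)
  expect_error(assemble_site(fx$ds, fx$dir), "overwrite")
  expect_s3_class(assemble_site(fx$ds, fx$dir, overwrite = TRUE),
                  "site_bundle")
})

test_that("a supplied template is copied into the site root", {
  tpl <- tempfile(); dir.create(file.path(tpl, "css"), recursive = TRUE)
  writeLines("<html>custom</html>", file.path(tpl, "index.html"))
  writeLines("body {}", file.path(tpl, "css", "style.css"))
  ds <- site_fixture(seed = 45)$ds
  b <- assemble_site(ds, tempfile(), template_dir = tpl)
  expect_identical(readLines(file.path(b$root, "index.html")),
                   "<html>custom</html>")
  expect_true("css/style.css" %in% b$manifest$path)
})

test_that("publish dry-run emits a schema-valid payload and a complete repo copy", {
  fx <- site_fixture(seed = 46)
  out <- tempfile()
  res <- publish_dryrun(fx$bundle, out)
  expect_identical(res$payload$n_subjects, 4L)
  expect_identical(res$payload$n_tracts, 2L)
  expect_identical(unlist(res$payload$metric_names), c("fa", "md"))
  schema <- jsonlite::read_json(
    system.file("schema", "publish-payload.schema.json",
                package = "tractometry"))
  expect_length(tractometry:::check_against_schema(res$payload, schema), 0L)
  # repo copy carries every manifest file byte-identically
  for (f in fx$bundle$manifest$path) {
    expect_identical(readBin(file.path(res$repo_dir, f), "raw", 1e6),
                     readBin(file.path(fx$bundle$root, f), "raw", 1e6),
                     label = f)
  }
  # idempotence
  res2 <- publish_dryrun(fx$bundle, out)
  expect_identical(readLines(res$payload_path), readLines(res2$payload_path))
})

test_that("the schema checker rejects structurally broken payloads", {
  schema <- jsonlite::read_json(
    system.file("schema", "publish-payload.schema.json",
                package = "tractometry"))
  good <- list(schema_version = "1.0", n_subjects = 2L, n_tracts = 1L,
               n_nodes = 10L, metric_names = list("fa"),
               tract_names = list("t"), files = list())
  expect_length(tractometry:::check_against_schema(good, schema), 0L)
  bad <- good; bad$n_subjects <- NULL
  expect_match(tractometry:::check_against_schema(bad, schema),
               "n_subjects", all = FALSE)
  bad2 <- good; bad2$metric_names <- list(1)
  expect_match(tractometry:::check_against_schema(bad2, schema),
               "metric_names", all = FALSE)
})
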