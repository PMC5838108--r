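"""Bridge between classic (v7) MATLAB MAT-files and an explicit JSON form.

Used by the R package for MAT dialects that predate the HDF5 layout; scipy.io
is the canonical reader/writer for those. The JSON schema is deliberately
explicit (flattened row-major matrices with nrow/ncol) so nothing depends on
JSON array-shape guessing on the R side.

Usage:
  python mat_bridge.py mat2json <in.mat> <out.json>
  python mat_bridge.py json2mat <in.json> <out.mat>
"""
import json
import sys

import numpy as np
import scipy.io


def _field(obj, name):
    """Case-insensitive attribute/key lookup on a loaded MAT struct."""
    if isinstance(obj, dict):
        keys = {k.lower(): k for k in obj.keys() if not k.startswith("__")}
        return obj[keys[name.lower()]] if name.lower() in keys else None
    names = getattr(obj, "_fieldnames", [])
    keys = {k.lower(): k for k in names}
    return getattr(obj, keys[name.lower()]) if name.lower() in keys else None


def _as_str_list(x):
    if x is None:
        return []
    arr = np.atleast_1d(np.asarray(x, dtype=object)).ravel()
    return [str(np.asarray(v).item()) if np.asarray(v).size == 1 else str(v)
            for v in arr]


def _as_matrix(x):
    m = np.asarray(x, dtype=float)
    if m.ndim == 1:
        m = m.reshape(1, -1)
    return m


def _matrix_json(m):
    data = [None if np.isnan(v) else float(v) for v in m.ravel(order="C")]
    return {"nrow": int(m.shape[0]), "ncol": int(m.shape[1]), "data": data}


def _jsonify_params(x):
    if x is None:
        return {}
    if isinstance(x, dict):
        return {k: _jsonify_params(v) for k, v in x.items()
                if not k.startswith("__")}
    if hasattr(x, "_fieldnames"):
        return {k: _jsonify_params(getattr(x, k)) for k in x._fieldnames}
    arr = np.asarray(x)
    if arr.dtype.kind in "fiub":
        vals = [None if (np.issubdtype(type(v), np.floating) and np.isnan(v))
                else v.item() for v in arr.ravel()]
        return vals[0] if len(vals) == 1 else vals
    if arr.dtype.kind in "US":
        vals = [str(v) for v in arr.ravel()]
        return vals[0] if len(vals) == 1 else vals
    if arr.dtype == object:
        vals = [_jsonify_params(v) for v in arr.ravel()]
        return vals[0] if len(vals) == 1 else vals
    return None


def mat2json(mat_path, json_path):
    mat = scipy.io.loadmat(mat_path, squeeze_me=True,
                           struct_as_record=False)
    afq = _field(mat, "afq")
    if afq is None:
        candidates = [k for k in mat if not k.startswith("__")]
        if len(candidates) == 1:
            afq = mat[candidates[0]]
        else:
            raise SystemExit("no 'afq' struct found in " + mat_path)

    sub_ids = _as_str_list(_field(afq, "sub_ids"))
    fgnames = _as_str_list(_field(afq, "fgnames"))
    vals = _field(afq, "vals")
    if vals is None or not fgnames or not sub_ids:
        raise SystemExit(
            "MAT file lacks required fields (vals, fgnames, sub_ids)")

    values = {}
    metric_names = (list(vals.keys()) if isinstance(vals, dict)
                    else list(vals._fieldnames))
    for metric in metric_names:
        per_tract = _field(vals, metric)
        arr = np.atleast_1d(np.asarray(per_tract, dtype=object)).ravel()
        if len(arr) == 1 and not isinstance(arr[0], np.ndarray) \
                and len(fgnames) == 1:
            arr = [per_tract]
        values[metric.lower()] = [_matrix_json(_as_matrix(m)) for m in arr]

    metadata = {}
    meta = _field(afq, "metadata")
    if meta is not None:
        cols = (list(meta.keys()) if isinstance(meta, dict)
                else list(getattr(meta, "_fieldnames", [])))
        for col in cols:
            v = _field(meta, col)
            arr = np.atleast_1d(np.asarray(v)).ravel()
            if arr.dtype.kind in "fiub":
                metadata[col] = {
                    "type": "numeric",
                    "values": [None if np.isnan(float(x)) else float(x)
                               for x in arr.astype(float)]}
            else:
                metadata[col] = {"type": "character",
                                 "values": _as_str_list(arr)}

    out = {"subject_ids": sub_ids, "tract_names": fgnames,
           "values": values, "metadata": metadata,
           "params": _jsonify_params(_field(afq, "params"))}
    with open(json_path, "w", encoding="utf-8") as fh:
        json.dump(out, fh, allow_nan=False)


def _param_to_mat(v):
    if isinstance(v, dict):
        return {k: _param_to_mat(x) for k, x in v.items()}
    if isinstance(v, list):
        if all(isinstance(x, (int, float)) or x is None for x in v):
            return np.array([np.nan if x is None else float(x) for x in v])
        return np.array([str(x) for x in v], dtype=object)
    if v is None:
        return np.nan
    return v


def json2mat(json_path, mat_path):
    with open(json_path, encoding="utf-8") as fh:
        spec = json.load(fh)
    vals = {}
    for metric, tracts in spec["values"].items():
        cell = np.empty(len(tracts), dtype=object)
        for i, m in enumerate(tracts):
            data = [np.nan if v is None else v for v in m["data"]]
            cell[i] = np.asarray(data, dtype=float).reshape(
                m["nrow"], m["ncol"])
        vals[metric] = cell
    metadata = {}
    for col, desc in spec.get("metadata", {}).items():
        if desc["type"] == "numeric":
            metadata[col] = np.array(
                [np.nan if v is None else float(v) for v in desc["values"]])
        else:
            metadata[col] = np.array(
                ["" if v is None else str(v) for v in desc["values"]],
                dtype=object)
    afq = {"sub_ids": np.array(spec["subject_ids"], dtype=object),
           "fgnames": np.array(spec["tract_names"], dtype=object),
           "vals": vals}
    if metadata:
        afq["metadata"] = metadata
    params = spec.get("params") or {}
    if params:
        afq["params"] = {k: _param_to_mat(v) for k, v in params.items()}
    scipy.io.savemat(mat_path, {"afq": afq}, format="5",
                     long_field_names=True, do_compression=False)


def main(argv):
    if len(argv) != 4 or argv[1] not in {"mat2json", "json2mat"}:
        raise SystemExit(__doc__)
    if argv[1] == "mat2json":
        mat2json(argv[2], argv[3])
    else:
        json2mat(argv[2], argv[3])


if __name__ == "__main__":
    main(sys.argv)
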