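"""Exchange bridge between velode's plain-text MTX directory layout and
HDF5-backed single-cell formats (h5ad via anndata, loom via h5py).

Usage:
    python h5_bridge.py to_exchange   <file.h5ad|file.loom> <exchange_dir>
    python h5_bridge.py from_exchange <exchange_dir> <file.h5ad|file.loom>

The exchange directory holds spliced.mtx / unspliced.mtx (genes x cells),
genes.tsv, barcodes.tsv and optionally modality.mtx + features.tsv,
labels.tsv, embedding.tsv. All numeric payloads stay text on the R side.
"""
import os
import sys

import numpy as np
import scipy.io as sio
import scipy.sparse as sp


def _dense(x):
    return np.asarray(x.todense()) if sp.issparse(x) else np.asarray(x)


def read_exchange(d):
    S = _dense(sio.mmread(os.path.join(d, "spliced.mtx"))).T  # cells x genes
    U = _dense(sio.mmread(os.path.join(d, "unspliced.mtx"))).T
    genes = [l.rstrip("\n") for l in open(os.path.join(d, "genes.tsv"))]
    cells = [l.rstrip("\n") for l in open(os.path.join(d, "barcodes.tsv"))]
    out = {"S": S, "U": U, "genes": genes, "cells": cells,
           "O": None, "labels": None, "emb": None}
    mpath = os.path.join(d, "modality.mtx")
    if os.path.exists(mpath):
        out["O"] = _dense(sio.mmread(mpath)).T
    lpath = os.path.join(d, "labels.tsv")
    if os.path.exists(lpath):
        out["labels"] = [l.rstrip("\n") for l in open(lpath)]
    epath = os.path.join(d, "embedding.tsv")
    if os.path.exists(epath):
        out["emb"] = np.loadtxt(epath, delimiter="\t", ndmin=2)
    return out


def write_exchange(d, S, U, genes, cells, O=None, labels=None, emb=None):
    os.makedirs(d, exist_ok=True)
    if S.shape != U.shape:
        sys.exit("shape-mismatch: spliced %s vs unspliced %s"
                 % (S.shape, U.shape))
    sio.mmwrite(os.path.join(d, "spliced.mtx"), sp.coo_matrix(S.T))
    sio.mmwrite(os.path.join(d, "unspliced.mtx"), sp.coo_matrix(U.T))
    open(os.path.join(d, "genes.tsv"), "w").write("\n".join(genes) + "\n")
    open(os.path.join(d, "barcodes.tsv"), "w").write("\n".join(cells) + "\n")
    if O is not None:
        sio.mmwrite(os.path.join(d, "modality.mtx"), sp.coo_matrix(O.T))
        feats = ["feat_%d" % (i + 1) for i in range(O.shape[1])]
        open(os.path.join(d, "features.tsv"), "w").write("\n".join(feats) + "\n")
    if labels is not None:
        open(os.path.join(d, "labels.tsv"), "w").write("\n".join(labels) + "\n")
    if emb is not None:
        np.savetxt(os.path.join(d, "embedding.tsv"), emb, delimiter="\t")


def h5ad_to_exchange(path, d):
    import anndata as ad
    a = ad.read_h5ad(path)
    for layer in ("spliced", "unspliced"):
        if layer not in a.layers:
            sys.exit("layer-missing: %s" % layer)
    S = _dense(a.layers["spliced"])
    U = _dense(a.layers["unspliced"])
    O = _dense(a.obsm["X_modality"]) if "X_modality" in a.obsm else None
    labels = (a.obs["cell_type"].astype(str).tolist()
              if "cell_type" in a.obs else None)
    emb = np.asarray(a.obsm["X_emb"]) if "X_emb" in a.obsm else None
    write_exchange(d, S, U, list(a.var_names), list(a.obs_names),
                   O=O, labels=labels, emb=emb)


def exchange_to_h5ad(d, path):
    import anndata as ad
    import pandas as pd
    x = read_exchange(d)
    a = ad.AnnData(X=x["S"].copy(),
                   obs=pd.DataFrame(index=x["cells"]),
                   var=pd.DataFrame(index=x["genes"]))
    a.layers["spliced"] = x["S"]
    a.layers["unspliced"] = x["U"]
    if x["O"] is not None:
        a.obsm["X_modality"] = x["O"]
    if x["labels"] is not None:
        a.obs["cell_type"] = x["labels"]
    if x["emb"] is not None:
        a.obsm["X_emb"] = x["emb"]
    a.write_h5ad(path)


def loom_to_exchange(path, d):
    import h5py
    with h5py.File(path, "r") as f:
        layers = f["layers"] if "layers" in f else {}
        missing = [l for l in ("spliced", "unspliced") if l not in layers]
        if missing:
            sys.exit("layer-missing: %s" % missing[0])
        # loom matrices are genes x cells
        S = np.asarray(layers["spliced"]).T
        U = np.asarray(layers["unspliced"]).T
        genes = [g.decode() if isinstance(g, bytes) else str(g)
                 for g in f["row_attrs"]["Gene"][:]]
        cells = [c.decode() if isinstance(c, bytes) else str(c)
                 for c in f["col_attrs"]["CellID"][:]]
    write_exchange(d, S, U, genes, cells)


def exchange_to_loom(d, path):
    import h5py
    x = read_exchange(d)
    with h5py.File(path, "w") as f:
        f.create_dataset("matrix", data=x["S"].T)
        g = f.create_group("layers")
        g.create_dataset("spliced", data=x["S"].T)
        g.create_dataset("unspliced", data=x["U"].T)
        ra = f.create_group("row_attrs")
        ra.create_dataset("Gene",
                          data=np.array(x["genes"], dtype="S"))
        ca = f.create_group("col_attrs")
        ca.create_dataset("CellID",
                          data=np.array(x["cells"], dtype="S"))


def main(argv):
    if len(argv) != 4:
        sys.exit("usage: h5_bridge.py to_exchange|from_exchange <src> <dst>")
    cmd, src, dst = argv[1], argv[2], argv[3]
    if cmd == "to_exchange":
        if src.endswith(".loom"):
            loom_to_exchange(src, dst)
        else:
            h5ad_to_exchange(src, dst)
    elif cmd == "from_exchange":
        if dst.endswith(".loom"):
            exchange_to_loom(src, dst)
        else:
            exchange_to_h5ad(src, dst)
    else:
        sys.exit("unknown command %s" % cmd)


if __name__ == "__main__":
    main(sys.argv)
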