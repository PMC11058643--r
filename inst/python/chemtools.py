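"""Batch chemistry helper backed by RDKit.

Reads SMILES (one per line) from an input file and writes a JSON document
to an output file. Subcommands:

  canonicalize  -> {"canonical": [str|null, ...]}
  properties    -> {"canonical": [...], "logP": [...], "MolWt": [...],
                    "QED": [...], "SAScore": [...]}  (null where invalid)
  tanimoto REF  -> {"similarity": [float|null, ...]}  ECFP4 (Morgan r=2,
                    2048 bits) Tanimoto against the reference SMILES REF,
                    read from a third positional argument (a file path).

Invalid SMILES never raise; they yield null so the caller decides policy.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, DataStructs, Descriptors, QED, RDConfig

sys.path.append(RDConfig.RDContribDir + "/SA_Score")
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")


def mol_of(smi):
    try:
        return Chem.MolFromSmiles(smi)
    except Exception:
        return None


def main():
    cmd, infile, outfile = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(infile) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    mols = [mol_of(s) for s in smiles]

    if cmd == "canonicalize":
        out = {"canonical": [Chem.MolToSmiles(m) if m else None for m in mols]}
    elif cmd == "properties":
        out = {"canonical": [], "logP": [], "MolWt": [], "QED": [], "SAScore": []}
        for m in mols:
            if m is None:
                for k in out:
                    out[k].append(None)
                continue
            out["canonical"].append(Chem.MolToSmiles(m))
            out["logP"].append(Crippen.MolLogP(m))
            out["MolWt"].append(Descriptors.MolWt(m))
            out["QED"].append(QED.qed(m))
            out["SAScore"].append(sascorer.calculateScore(m))
    elif cmd == "tanimoto":
        with open(sys.argv[4]) as fh:
            ref_smiles = fh.read().strip()
        ref = mol_of(ref_smiles)
        if ref is None:
            sys.stderr.write("invalid reference SMILES\n")
            sys.exit(2)
        ref_fp = AllChem.GetMorganFingerprintAsBitVect(ref, 2, nBits=2048)
        sims = []
        for m in mols:
            if m is None:
                sims.append(None)
            else:
                fp = AllChem.GetMorganFingerprintAsBitVect(m, 2, nBits=2048)
                sims.append(DataStructs.TanimotoSimilarity(ref_fp, fp))
        out = {"similarity": sims}
    else:
        sys.stderr.write(f"unknown subcommand {cmd}\n")
        sys.exit(2)

    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
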