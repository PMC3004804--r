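"""Circular-fingerprint + descriptor featurizer (RDKit back end).

Called by cytobayes::featurize_smiles(). Reads a headerless TSV of
(id, smiles) rows, writes a TSV with columns:
  id  status  features  alogp  mw  hbd  hba  rotb  fpsa
status is "ok" or a parse-error message; features is a space-separated
list of hashed feature ids (unfolded, or folded modulo fold_size).
Usage: python fcfp.py IN OUT RADIUS {functional|connectivity} FOLD_SIZE
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, Lipinski, rdMolDescriptors
from rdkit.Chem import rdFingerprintGenerator as rfg

RDLogger.DisableLog("rdApp.*")


def main(fin, fout, radius, invariants, fold_size):
    if invariants == "functional":
        inv = rfg.GetMorganFeatureAtomInvGen()
        gen = rfg.GetMorganGenerator(radius=radius, atomInvariantsGenerator=inv)
    else:
        gen = rfg.GetMorganGenerator(radius=radius)
    with open(fin) as fh, open(fout, "w") as out:
        out.write("id\tstatus\tfeatures\talogp\tmw\thbd\thba\trotb\tfpsa\n")
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                out.write(f"{ident}\tunparsable SMILES\t\t\t\t\t\t\t\n")
                continue
            keys = sorted(gen.GetSparseCountFingerprint(mol).GetNonzeroElements())
            if fold_size:
                keys = sorted({k % fold_size for k in keys})
            tpsa = rdMolDescriptors.CalcTPSA(mol)
            asa = rdMolDescriptors.CalcLabuteASA(mol)
            # fragment TPSA can slightly exceed the Labute area estimate
            # for tiny polar molecules; the fraction is clamped to [0, 1]
            fpsa = min(1.0, tpsa / asa) if asa > 0 else 0.0
            row = [
                ident,
                "ok",
                " ".join(str(k) for k in keys),
                f"{Crippen.MolLogP(mol):.6g}",
                f"{Descriptors.MolWt(mol):.6g}",
                str(Lipinski.NumHDonors(mol)),
                str(Lipinski.NumHAcceptors(mol)),
                str(Descriptors.NumRotatableBonds(mol)),
                f"{fpsa:.6g}",
            ]
            out.write("\t".join(row) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], int(sys.argv[3]), sys.argv[4], int(sys.argv[5]))
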