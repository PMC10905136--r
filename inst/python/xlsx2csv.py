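"""Dump every sheet of an .xlsx workbook to <out_dir>/<sheet>.csv."""
import csv
import re
import sys

import openpyxl


def main(path, out_dir):
    wb = openpyxl.load_workbook(path, read_only=True, data_only=True)
    for ws in wb.worksheets:
        name = re.sub(r"[^A-Za-z0-9_-]+", "_", ws.title)
        with open(f"{out_dir}/{name}.csv", "w", newline="") as fh:
            writer = csv.writer(fh)
            for row in ws.iter_rows(values_only=True):
                writer.writerow(["" if v is None else v for v in row])


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
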