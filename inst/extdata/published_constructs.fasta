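>M0 no mutations
NSIKTLSKKAVLLAQEGKAEEAIKIMRKAVSLDPNNIKTLSKKAVLLAQEGKAEEAIKIMRK
AVSLDPNNIKTLSKKAVLLAQEGKAEEAIKIMRKAVSLIDKAAKGSTLHKNAAARRKSRLMR
KVQKL
>M2 K7L I23Y
NSIKTLSKLAVLLAQEGKAEEAIKYMRKAVSLDPNNIKTLSKLAVLLAQEGKAEEAIKYMRK
AVSLDPNNIKTLSKLAVLLAQEGKAEEAIKYMRKAVSLIDKAAKGSTLHKNAAARRKSRLMR
KVQKL
>M4E K2E K7L V9N I23Y
NSIETLSKLANLLAQEGKAEEAIKYMRKAVSLDPNNIETLSKLANLLAQEGKAEEAIKYMRK
AVSLDPNNIETLSKLAVLLAQEGKAEEAIKYMRKAVSLIDKAAKGSTLHKNAAARRKSRLMR
KVQKL
>M4N K6N K7L V9N I23Y
NSIKTLSNLANLLAQEGKAEEAIKYMRKAVSLDPNNIKTLSNLANLLAQEGKAEEAIKYMRK
AVSLDPNNIKTLSNLAVLLAQEGKAEEAIKYMRKAVSLIDKAAKGSTLHKNAAARRKSRLMR
KVQKL
>M4RD K2E K7R V9N I23D
NSIETLSKRANLLAQEGKAEEAIKDMRKAVSLDPNNIETLSKRANLLAQEGKAEEAIKDMRK
AVSLDPNNIETLSKRAVLLAQEGKAEEAIKDMRKAVSLIDKAAKGSTLHKNAAARRKSRLMR
KVQKL
>M5 K2E L4W K7L V9N I23Y
NSIETLSKLANLLAQEGKAEEAIKYMRKAVSLDPNNIETWSKLANLLAQEGKAEEAIKYMRK
AVSLDPNNIETWSKLAVLLAQEGKAEEAIKYMRKAVSLIDKAAKGSTLHKNAAARRKSRLMR
KVQKL
>M4NdC M4N without stop helix
NSIKTLSNLANLLAQEGKAEEAIKYMRKAVSLDPNNIKTLSNLANLLAQEGKAEEAIKYMRK
AVSLDPNNIKTLSNLAVLLAQEGKAEEAIKYMRKAVSLIDKAAK
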