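// Reference=MNI
// Example foci table in the community text dialect.

// Smith 2009 social judgment: n=14
-2.00 48.00 28.00
-6.00 -52.00 28.00
50.00 -62.00 12.00

// Jones 2011 mentalizing: n=21
4.00 46.00 30.00
-48.00 -58.00 18.00

// Lee 2010 theory of mind: n=12
0.00 52.00 22.00
-4.00 -54.00 24.00
54.00 -58.00 16.00
-50.00 -6.00 -18.00
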