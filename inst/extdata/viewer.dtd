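<!-- Viewer dialect: per-viewer gaze captures. `joint` is the body-part
     AOI under the gaze ("" = off the character); `n` optionally declares
     the sample count for validation. -->
<!ELEMENT viewer (capture*)>
<!ATTLIST viewer id CDATA #REQUIRED>
<!ELEMENT capture (sample*)>
<!ATTLIST capture
  media CDATA #REQUIRED
  order CDATA #REQUIRED
  n     CDATA #IMPLIED>
<!ELEMENT sample EMPTY>
<!ATTLIST sample
  t     CDATA #REQUIRED
  x     CDATA #REQUIRED
  y     CDATA #REQUIRED
  joint CDATA "">
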