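<!-- Experiment dialect: media sources with optional intervals, an optional
     temporal reference mapping, and a per-source skeleton payload. -->
<!ELEMENT experiment (source*)>
<!ELEMENT source (interval*, mapping?, (skeleton2d | motion3d)?)>
<!ATTLIST source
  name     CDATA #REQUIRED
  duration CDATA #REQUIRED
  format   (none|skeleton2d|motion3d) "none">
<!ELEMENT interval EMPTY>
<!ATTLIST interval
  start CDATA #REQUIRED
  end   CDATA #REQUIRED>
<!ELEMENT mapping EMPTY>
<!ATTLIST mapping reference CDATA #REQUIRED>
<!ELEMENT skeleton2d (joint*, bone*)>
<!ATTLIST skeleton2d
  fps       CDATA #REQUIRED
  keyframes CDATA #REQUIRED>
<!ELEMENT joint EMPTY>
<!ATTLIST joint
  name   CDATA #REQUIRED
  parent CDATA "">
<!ELEMENT bone EMPTY>
<!ATTLIST bone
  a     CDATA #REQUIRED
  b     CDATA #REQUIRED
  width CDATA #REQUIRED
  depth CDATA #REQUIRED>
<!ELEMENT motion3d EMPTY>
<!ATTLIST motion3d file CDATA #REQUIRED>
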