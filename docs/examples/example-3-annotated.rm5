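<?xml version="1.0" encoding="UTF-8"?>
<!-- Hand-annotated example of the supported .rm5 dialect (see ../rm5-dialect.md).
     Comments like this one are legal anywhere; the reader preserves comments
     inside free-text fields and ignores them elsewhere. -->
<COCHRANE_REVIEW REVIEW_ID="EXAMPLE03" VERSION="5.3">
  <COVER_SHEET>
    <TITLE>Example drug versus placebo for schizophrenia</TITLE>
  </COVER_SHEET>
  <STUDIES_AND_REFERENCES>
    <STUDIES>
      <INCLUDED_STUDIES>
        <!-- study ids follow the "Surname YYYY" convention; the year is
             parsed from the id for publication-year statistics -->
        <STUDY ID="Smith 1999" NAME="Smith 1999">
          <!-- many-to-one reports: two references, one underlying study -->
          <REFERENCE ID="REF-Smith-1999-1">
            <TI>Primary report of the Smith trial</TI>
            <SO>J Clin Psychiatry</SO>
            <YR>1999</YR>
          </REFERENCE>
          <REFERENCE ID="REF-Smith-1999-2">
            <TI>Two-year follow-up of the Smith trial</TI>
            <YR>2001</YR>
            <!-- SO (journal) is optional and omitted here -->
          </REFERENCE>
        </STUDY>
        <STUDY ID="Jones 2005" NAME="Jones 2005">
          <REFERENCE ID="REF-Jones-2005-1">
            <TI>Jones randomised trial report</TI>
            <SO>Schizophr Res</SO>
            <YR>2005</YR>
          </REFERENCE>
        </STUDY>
      </INCLUDED_STUDIES>
      <!-- subtrees outside the supported subset, like this excluded-studies
           section, are retained opaquely and re-emitted on write -->
      <EXCLUDED_STUDIES>
        <STUDY ID="Gone 1990" NAME="Gone 1990"/>
      </EXCLUDED_STUDIES>
    </STUDIES>
  </STUDIES_AND_REFERENCES>
  <CHARACTERISTICS_OF_STUDIES>
    <CHARACTERISTICS_OF_INCLUDED_STUDIES>
      <INCLUDED_CHAR STUDY_ID="Smith 1999">
        <!-- five fixed free-text fields; inline markup is preserved verbatim,
             matching happens on a plain-text projection -->
        <CHAR_METHODS><P>Allocation: randomised. Blinding: double-blind. Duration: 12 weeks.</P></CHAR_METHODS>
        <CHAR_PARTICIPANTS><P>N=60 inpatients with schizophrenia.</P></CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS><P>1. Example drug 300 mg/day. 2. Placebo.</P></CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES><P>Relapse; mental state (BPRS).</P></CHAR_OUTCOMES>
        <!-- CHAR_NOTES omitted: empty fields are not serialized -->
      </INCLUDED_CHAR>
      <INCLUDED_CHAR STUDY_ID="Jones 2005">
        <CHAR_METHODS><P>Quasi-randomised by alternation. Open label.</P></CHAR_METHODS>
        <CHAR_PARTICIPANTS><P>120 outpatients enrolled.</P></CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS><P>Example drug versus placebo.</P></CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES><P>Leaving the study early.</P></CHAR_OUTCOMES>
        <CHAR_NOTES><P>Industry funded.</P></CHAR_NOTES>
      </INCLUDED_CHAR>
    </CHARACTERISTICS_OF_INCLUDED_STUDIES>
  </CHARACTERISTICS_OF_STUDIES>
  <QUALITY_ITEMS>
    <!-- risk-of-bias table: one item per bias domain, one entry per study;
         RESULT is LOW, HIGH or UNCLEAR -->
    <QUALITY_ITEM NAME="Allocation concealment">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Smith 1999" RESULT="LOW">
        <DESCRIPTION>Central pharmacy allocation.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Jones 2005" RESULT="HIGH">
        <DESCRIPTION>Alternation is not concealed.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
  </QUALITY_ITEMS>
  <ANALYSES_AND_DATA>
    <COMPARISON ID="EXAMPLE03.CMP01" NAME="Example drug versus placebo">
      <!-- dichotomous outcome: events/total per arm, events <= total -->
      <DICH_OUTCOME ID="EXAMPLE03.CMP01.O001" NAME="Global state: relapse">
        <DICH_DATA STUDY_ID="Smith 1999" EVENTS_1="5" TOTAL_1="30" EVENTS_2="11" TOTAL_2="30"/>
        <DICH_DATA STUDY_ID="Jones 2005" EVENTS_1="14" TOTAL_1="60" EVENTS_2="19" TOTAL_2="60"/>
      </DICH_OUTCOME>
      <!-- continuous outcome: mean/sd/n per arm -->
      <CONT_OUTCOME ID="EXAMPLE03.CMP01.O002" NAME="Mental state: average endpoint score (BPRS)">
        <CONT_DATA STUDY_ID="Smith 1999" MEAN_1="38.2" SD_1="9.5" TOTAL_1="30" MEAN_2="44.7" SD_2="10.1" TOTAL_2="30"/>
      </CONT_OUTCOME>
    </COMPARISON>
  </ANALYSES_AND_DATA>
</COCHRANE_REVIEW>
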